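# Independent oracle implementations and small geometric fixtures used
# across the test files. Everything here is deliberately written as a
# different algorithm (or brute force) from the package code paths it checks.

vnorm_test <- function(v) sqrt(sum(v^2))

# Apply a transform via an explicitly built 4x4 homogeneous matrix.
homogeneous_apply <- function(transform, pts) {
  H <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  p <- cbind(as.matrix(pts), 1)
  out <- p %*% t(H)
  out[, 1:3, drop = FALSE]
}

# Objective of the landmark Procrustes problem at a given rotation, with the
# translation eliminated in closed form (centroid alignment).
centered_objective <- function(R, src, dst) {
  sc <- sweep(src, 2, colMeans(src))
  dc <- sweep(dst, 2, colMeans(dst))
  sum((sc %*% t(R) - dc)^2)
}

# Brute-force rotation search: coarse uniform axis/angle grid followed by
# two local refinement rounds (still pure grid search, no SVD anywhere).
# For a fixed axis the objective is linear in cos/sin of the angle, which
# lets a whole angle sweep be evaluated vectorized.
grid_procrustes_objective <- function(src, dst, n_axes = 300L, rounds = 8L) {
  sc <- sweep(src, 2, colMeans(src))
  dc <- sweep(dst, 2, colMeans(dst))
  base <- sum(sc^2) + sum(dc^2)
  axis_objective <- function(k, angles) {
    th <- angles * pi / 180
    ks <- sc %*% k                       # k . s_i
    kxs <- cbind(k[2] * sc[, 3] - k[3] * sc[, 2],
                 k[3] * sc[, 1] - k[1] * sc[, 3],
                 k[1] * sc[, 2] - k[2] * sc[, 1])
    # d . R(th) s = cos(th) d.s + sin(th) d.(k x s) + (1 - cos(th)) (d.k)(k.s)
    c0 <- sum(rowSums(dc * sc))
    c1 <- sum(rowSums(dc * kxs))
    c2 <- sum((dc %*% k) * ks)
    cross_term <- cos(th) * c0 + sin(th) * c1 + (1 - cos(th)) * c2
    list(obj = base - 2 * cross_term, angles = angles)
  }
  axes <- matrix(rnorm(3L * n_axes), n_axes, 3L)
  axes <- axes / sqrt(rowSums(axes^2))
  best <- list(obj = Inf, axis = c(0, 0, 1), angle = 0)
  sweep_axes <- function(axes, angles) {
    for (r in seq_len(nrow(axes))) {
      res <- axis_objective(axes[r, ], angles)
      j <- which.min(res$obj)
      if (res$obj[j] < best$obj) {
        best <<- list(obj = res$obj[j], axis = axes[r, ], angle = res$angles[j])
      }
    }
  }
  # a 0.25-degree angle sweep is already far below the 1% objective
  # tolerance, so only the axis needs progressive refinement
  fine_angles <- seq(0, 360, by = 0.25)
  sweep_axes(axes, fine_angles)
  spread <- 0.4
  for (round in seq_len(rounds)) {
    local <- matrix(rnorm(3L * 150L, sd = spread), 150L, 3L)
    local <- sweep(local, 2, best$axis, `+`)
    local <- rbind(best$axis, local / sqrt(rowSums(local^2)))
    sweep_axes(local, fine_angles)
    spread <- spread / 2.5
  }
  best$obj
}

# Horn's closed-form absolute orientation via the quaternion eigenproblem —
# an algebraically independent solution of the same least-squares problem.
horn_quaternion_fit <- function(src, dst) {
  sc <- sweep(src, 2, colMeans(src))
  dc <- sweep(dst, 2, colMeans(dst))
  M <- crossprod(sc, dc)
  N <- matrix(0, 4, 4)
  N[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  N[1, 2] <- N[2, 1] <- M[2, 3] - M[3, 2]
  N[1, 3] <- N[3, 1] <- M[3, 1] - M[1, 3]
  N[1, 4] <- N[4, 1] <- M[1, 2] - M[2, 1]
  N[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  N[2, 3] <- N[3, 2] <- M[1, 2] + M[2, 1]
  N[2, 4] <- N[4, 2] <- M[3, 1] + M[1, 3]
  N[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  N[3, 4] <- N[4, 3] <- M[2, 3] + M[3, 2]
  N[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),  2 * (x * z + w * y),
    2 * (x * y + w * z),  w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),  2 * (y * z + w * x),  w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  t <- colMeans(dst) - drop(R %*% colMeans(src))
  list(rotation = R, translation = t)
}

# Independent point-to-triangle distance: project onto the triangle's plane,
# accept the foot point if its barycentric coordinates are non-negative,
# otherwise take the minimum distance to the three edge segments. Vectorized
# over triangles for one query point.
point_triangles_distance <- function(p, A, B, C) {
  seg_d2 <- function(P0, P1) {
    d <- P1 - P0
    w <- matrix(p, nrow(P0), 3, byrow = TRUE) - P0
    t <- pmin(1, pmax(0, rowSums(w * d) / pmax(rowSums(d * d), 1e-300)))
    rowSums((w - d * t)^2)
  }
  n <- cbind((B[, 2] - A[, 2]) * (C[, 3] - A[, 3]) - (B[, 3] - A[, 3]) * (C[, 2] - A[, 2]),
             (B[, 3] - A[, 3]) * (C[, 1] - A[, 1]) - (B[, 1] - A[, 1]) * (C[, 3] - A[, 3]),
             (B[, 1] - A[, 1]) * (C[, 2] - A[, 2]) - (B[, 2] - A[, 2]) * (C[, 1] - A[, 1]))
  ap <- matrix(p, nrow(A), 3, byrow = TRUE) - A
  h <- rowSums(ap * n) / rowSums(n * n)
  q <- matrix(p, nrow(A), 3, byrow = TRUE) - n * h   # foot point in plane
  # barycentric via areas against the (unnormalized) normal
  bary <- function(P0, P1) {
    e <- P1 - P0
    w <- q - P0
    rowSums(n * cbind(e[, 2] * w[, 3] - e[, 3] * w[, 2],
                      e[, 3] * w[, 1] - e[, 1] * w[, 3],
                      e[, 1] * w[, 2] - e[, 2] * w[, 1]))
  }
  inside <- bary(A, B) >= 0 & bary(B, C) >= 0 & bary(C, A) >= 0
  d2 <- pmin(seg_d2(A, B), seg_d2(B, C), seg_d2(C, A))
  d2[inside] <- pmin(d2[inside], rowSums((q - matrix(p, nrow(A), 3, byrow = TRUE))^2)[inside])
  sqrt(d2)
}

# Exhaustive nearest vertex / nearest surface point for a set of queries.
exhaustive_closest <- function(pts, surface, mode) {
  V <- surface$vertices; F <- surface$faces
  A <- V[F[, 1], , drop = FALSE]; B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  t(vapply(seq_len(nrow(pts)), function(i) {
    if (mode == "vertex") {
      d <- sqrt(rowSums(sweep(V, 2, pts[i, ])^2))
    } else {
      d <- point_triangles_distance(pts[i, ], A, B, C)
    }
    c(which.min(d), min(d))
  }, numeric(2)))
}

# Exhaustive two-sided Wilcoxon signed-rank p-value by enumerating all 2^n
# sign assignments of the (zero-stripped, midranked) differences.
enumeration_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- drop(signs %*% r)
  p_le <- mean(ws <= w + 1e-12)
  p_ge <- mean(ws >= w - 1e-12)
  list(statistic = w, p_value = min(1, 2 * min(p_le, p_ge)))
}

# Area of the lens formed by two circles of equal radius r with center
# separation d (closed form).
circle_lens_area <- function(r, d) {
  if (d >= 2 * r) return(0)
  2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
}

# A flat square plate at z = 0 spanning [-half, half]^2, triangulated on a
# regular grid.
make_plate <- function(half = 50, n = 11L) {
  g <- seq(-half, half, length.out = n)
  verts <- as.matrix(expand.grid(x = g, y = g))
  verts <- cbind(verts, z = 0)
  faces <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq_len(n - 1L)) {
      v1 <- (j - 1L) * n + i; v2 <- v1 + 1L
      v3 <- v1 + n; v4 <- v3 + 1L
      faces <- rbind(faces, c(v1, v2, v4), c(v1, v4, v3))
    }
  }
  endocardial_surface(verts, faces)
}

# Axis-aligned cube of given side, centered at the origin, 12 triangles.
make_cube <- function(side = 20) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -h
    c(5, 6, 7), c(6, 8, 7),   # z = +h
    c(1, 2, 5), c(2, 6, 5),   # y = -h
    c(3, 7, 4), c(4, 7, 8),   # y = +h
    c(1, 5, 3), c(3, 5, 7),   # x = -h
    c(2, 4, 6), c(4, 8, 6)    # x = +h
  )
  endocardial_surface(v, f)
}

# Icosphere-based sphere surface of radius r centered at `center`.
make_sphere <- function(r = 20, center = c(0, 0, 0), level = 3L) {
  ic <- icosphere(level)
  endocardial_surface(sweep(ic$vertices * r, 2, center, `+`), ic$faces)
}

# A generic, well-separated landmark set plus a randomly perturbed copy.
random_landmarks <- function(jitter = 0) {
  base <- rbind(c(0, 0, -80), c(0, 0, 0), c(25, 0, 5))
  m <- base + matrix(rnorm(9, sd = jitter), 3, 3)
  landmark_set(m[1, ], m[2, ], m[3, ])
}
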