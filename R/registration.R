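# The three rigid registration methods mapping one modality's LV dataset
# into the other's frame: landmark Procrustes, surface ICP, and
# three-chamber (anatomical frame) alignment.

# Least-squares proper rigid fit (Kabsch): the rotation + translation
# minimizing sum ||R s_i + t - d_i||^2 over corresponding rows. The smallest
# singular direction is sign-corrected so det(R) = +1 (no reflection).
kabsch_fit <- function(src, dst) {
  src <- as_points_matrix(src); dst <- as_points_matrix(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3L)
  sc <- colMeans(src); dc <- colMeans(dst)
  H <- crossprod(sweep(src, 2, sc), sweep(dst, 2, dc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # re-orthonormalize against accumulated round-off before validation
  sv2 <- svd(R)
  R <- sv2$u %*% t(sv2$v)
  rigid_transform(R, dc - drop(R %*% sc))
}

#' Landmark distance minimization (rigid Procrustes alignment)
#'
#' Finds the proper rigid transform (no scaling, no reflection) minimizing
#' the sum of squared distances between the three corresponding landmarks
#' (apex, mitral valve center, outflow tract) of the moving (`src`) and
#' fixed (`dst`) datasets, via the closed-form Kabsch/SVD solution.
#'
#' @param src,dst `landmark_set` objects (moving and fixed).
#' @return A `rigid_transform` mapping `src` coordinates into the `dst` frame.
#' @examples
#' lm <- landmark_set(c(0, 0, 80), c(0, 0, 0), c(30, 0, 10))
#' G <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(10, -5, 2))
#' procrustes_align(lm, transform_landmarks(G, lm))  # recovers G
#' @export
procrustes_align <- function(src, dst) {
  stopifnot(is_landmark_set(src), is_landmark_set(dst))
  if (landmark_triangle_area(src) <= LANDMARK_AREA_TOL ||
      landmark_triangle_area(dst) <= LANDMARK_AREA_TOL) {
    stop_degenerate("collinear landmark set: rigid Procrustes fit is not unique")
  }
  kabsch_fit(landmark_matrix(src), landmark_matrix(dst))
}

#' ICP parameters
#'
#' @param max_iterations maximum ICP iterations (>= 1).
#' @param convergence_tol convergence threshold on the absolute change of the
#'   RMS point-pair distance between iterations, mm.
#' @param correspondence_mode `"vertex"` pairs each moving vertex with the
#'   nearest fixed vertex; `"triangle"` with the nearest point on the fixed
#'   triangulated surface.
#' @return list of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, convergence_tol = 1e-4,
                       correspondence_mode = c("vertex", "triangle")) {
  correspondence_mode <- match.arg(correspondence_mode)
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop_data("max_iterations must be >= 1")
  if (!is.finite(convergence_tol) || convergence_tol <= 0) {
    stop_data("convergence_tol must be > 0")
  }
  structure(list(max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 correspondence_mode = correspondence_mode),
            class = "icp_params")
}

# Closest points on a set of triangles for a block of query points
# (Ericson's region classification, fully vectorized over query/triangle
# pairs). A, B, C, P are k x 3 matrices; returns closest point q and squared
# distance for each row.
closest_on_triangles_block <- function(A, B, C, P) {
  AB <- B - A; AC <- C - A
  AP <- P - A
  d1 <- rowSums(AB * AP); d2 <- rowSums(AC * AP)
  BP <- P - B
  d3 <- rowSums(AB * BP); d4 <- rowSums(AC * BP)
  CP <- P - C
  d5 <- rowSums(AB * CP); d6 <- rowSums(AC * CP)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  k <- nrow(P)
  q <- matrix(NA_real_, k, 3L)
  done <- logical(k)

  set_q <- function(mask, pts) {
    mask <- mask & !done
    if (any(mask)) {
      q[mask, ] <<- pts[mask, , drop = FALSE]
      done[mask] <<- TRUE
    }
  }
  set_q(d1 <= 0 & d2 <= 0, A)                                   # vertex A
  set_q(d3 >= 0 & d4 <= d3, B)                                  # vertex B
  set_q(d6 >= 0 & d5 <= d6, C)                                  # vertex C
  v_ab <- d1 / (d1 - d3)
  set_q(vc <= 0 & d1 >= 0 & d3 <= 0, A + AB * v_ab)             # edge AB
  w_ac <- d2 / (d2 - d6)
  set_q(vb <= 0 & d2 >= 0 & d6 <= 0, A + AC * w_ac)             # edge AC
  w_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_q(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + (C - B) * w_bc)  # edge BC
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom                              # interior
  set_q(!done, A + AB * v + AC * w)

  list(q = q, d2 = rowSums((P - q)^2))
}

# Nearest fixed vertex for each query point; ties broken by lowest index.
nearest_vertices <- function(pts, vertices) {
  pts <- as_points_matrix(pts)
  d2 <- outer(rowSums(pts^2), rep(1, nrow(vertices))) -
    2 * tcrossprod(pts, vertices) +
    outer(rep(1, nrow(pts)), rowSums(vertices^2))
  idx <- max.col(-d2, ties.method = "first")
  list(index = idx,
       closest = vertices[idx, , drop = FALSE],
       distance = sqrt(pmax(0, d2[cbind(seq_len(nrow(pts)), idx)])))
}

# Nearest point on the triangulated surface for each query point; ties
# broken by lowest triangle index. Exact: a cheap nearest-vertex upper bound
# prunes candidate triangles via the bound
#   dist(p, triangle) >= dist(p, centroid) - circumscribing radius,
# and the exact point-triangle distance is evaluated on the survivors only.
# The nearest vertex's own triangles always survive, so candidates are never
# empty and the true minimizer is never pruned.
nearest_surface_points <- function(pts, surface) {
  pts <- as_points_matrix(pts)
  V <- surface$vertices; F <- surface$faces
  n <- nrow(pts); m <- nrow(F)
  A <- V[F[, 1L], , drop = FALSE]
  B <- V[F[, 2L], , drop = FALSE]
  C <- V[F[, 3L], , drop = FALSE]
  cen <- (A + B + C) / 3
  rad <- sqrt(pmax(rowSums((A - cen)^2), rowSums((B - cen)^2),
                   rowSums((C - cen)^2)))
  ub <- nearest_vertices(pts, V)$distance
  dcen <- sqrt(pmax(0, outer(rowSums(pts^2), rep(1, m)) -
                      2 * tcrossprod(pts, cen) +
                      outer(rep(1, n), rowSums(cen^2))))
  cand <- which(dcen - rep(rad, each = n) <= ub + 1e-9)
  ip <- (cand - 1L) %% n + 1L
  it <- (cand - 1L) %/% n + 1L
  res <- closest_on_triangles_block(A[it, , drop = FALSE], B[it, , drop = FALSE],
                                    C[it, , drop = FALSE],
                                    pts[ip, , drop = FALSE])
  ord <- order(ip, res$d2, it)
  first <- ord[!duplicated(ip[ord])]
  sel <- first[order(ip[first])]
  list(index = it[sel], closest = res$q[sel, , drop = FALSE],
       distance = sqrt(pmax(0, res$d2[sel])))
}

#' Closest-point correspondences between points and a surface
#'
#' For each query point, the nearest vertex of the surface
#' (`mode = "vertex"`) or the nearest point on any of its triangles
#' (`mode = "triangle"`). Results equal exhaustive search; ties are broken
#' by the lowest vertex/triangle index, so output is deterministic.
#'
#' @param pts n x 3 matrix of query points (mm).
#' @param surface an `endocardial_surface`.
#' @param mode `"vertex"` or `"triangle"`.
#' @return list with `query` (n x 3), `closest` (n x 3), `distance`
#'   (n, mm) and `index` (vertex or triangle index).
#' @export
closest_point_pairs <- function(pts, surface, mode = c("vertex", "triangle")) {
  mode <- match.arg(mode)
  stopifnot(is_endocardial_surface(surface))
  pts <- as_points_matrix(pts)
  res <- if (mode == "vertex") nearest_vertices(pts, surface$vertices)
         else nearest_surface_points(pts, surface)
  c(list(query = pts), res)
}

#' Endocardial-surface ICP alignment
#'
#' Iterative closest point registration of the moving endocardial surface to
#' the fixed one. The surfaces are first registered with the landmark
#' Procrustes fit ([procrustes_align()]); each iteration then pairs every
#' transformed moving vertex with its closest point on the fixed surface (per
#' `correspondence_mode`) and re-solves the proper rigid transform minimizing
#' the mean squared pair distance, until the RMS objective change drops below
#' `convergence_tol` or `max_iterations` is reached.
#'
#' @param src_surface,dst_surface moving and fixed `endocardial_surface`.
#' @param src_lm,dst_lm moving and fixed `landmark_set` (for initialization).
#' @param params an [icp_params()] object.
#' @return list with `transform` (the final cumulative `rigid_transform`)
#'   and `trace`: `objective` (RMS pair distance per iteration, mm — a
#'   non-increasing sequence), `initial_objective` (RMS after the landmark
#'   initialization), `iterations_run`, `converged`.
#' @export
icp_align <- function(src_surface, dst_surface, src_lm, dst_lm,
                      params = icp_params()) {
  stopifnot(is_endocardial_surface(src_surface),
            is_endocardial_surface(dst_surface),
            inherits(params, "icp_params"))
  src <- src_surface$vertices
  if (nrow(src) < 4L || nrow(dst_surface$vertices) < 4L) {
    stop_data("ICP needs at least 4 vertices per surface")
  }
  nearest <- function(p) {
    if (params$correspondence_mode == "vertex") {
      nearest_vertices(p, dst_surface$vertices)
    } else {
      nearest_surface_points(p, dst_surface)
    }
  }
  transform <- procrustes_align(src_lm, dst_lm)
  cp <- nearest(apply_transform(transform, src))
  obj_prev <- sqrt(mean(cp$distance^2))
  initial_objective <- obj_prev
  objective <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  while (iterations < params$max_iterations) {
    iterations <- iterations + 1L
    transform <- kabsch_fit(src, cp$closest)
    obj <- sqrt(mean(rowSums((apply_transform(transform, src) - cp$closest)^2)))
    objective <- c(objective, obj)
    if (abs(obj_prev - obj) < params$convergence_tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
    cp <- nearest(apply_transform(transform, src))
  }
  list(transform = transform,
       trace = list(objective = objective,
                    initial_objective = initial_objective,
                    iterations_run = iterations,
                    converged = converged))
}

#' Three-chamber alignment
#'
#' The unique proper rigid transform making (1) the mitral valve centers
#' coincide, (2) the long axes (mitral center to apex) collinear and
#' co-directed, and (3) the three-chamber planes (through apex, mitral center
#' and outflow tract) coincident with the outflow tracts on the same side.
#' Realized as an anatomical frame-to-frame mapping
#' `T = Frame(dst) o Frame(src)^-1` using [build_frame()].
#'
#' @param src,dst moving and fixed `landmark_set` objects.
#' @return A `rigid_transform` mapping `src` coordinates into the `dst` frame.
#' @export
three_chamber_align <- function(src, dst) {
  stopifnot(is_landmark_set(src), is_landmark_set(dst))
  fd <- frame_as_transform(build_frame(dst))
  fs <- frame_as_transform(build_frame(src))
  compose_transforms(fd, invert_transform(fs))
}

#' Sample a random rigid transform
#'
#' Rotation: axis uniform on the sphere, angle uniform in
#' `[0, rotation_range]` degrees. Translation: direction uniform on the
#' sphere, magnitude uniform in `[0, translation_range]` mm. Draws from the
#' current RNG stream (seed with [set.seed()] for reproducibility).
#'
#' @param rotation_range max rotation angle, degrees.
#' @param translation_range max translation magnitude, mm.
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(rotation_range = 30, translation_range = 20) {
  axis <- unitize(stats::rnorm(3), "rotation axis")
  angle <- stats::runif(1, 0, rotation_range)
  dir <- unitize(stats::rnorm(3), "translation direction")
  mag <- stats::runif(1, 0, translation_range)
  rigid_transform(rotation_about_axis(axis, angle), dir * mag)
}
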