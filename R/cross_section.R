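# Plane-mesh cross-sections and 2-D polygon area/intersection machinery
# behind the three-chamber Dice coefficient.

PLANE_EPS <- 1e-9

as_plane <- function(plane) {
  if (!is.list(plane) || is.null(plane$point) || is.null(plane$normal)) {
    stop_data("plane must be a list(point=, normal=)")
  }
  list(point = as_point3(plane$point, "plane point"),
       normal = unitize(as_point3(plane$normal, "plane normal"), "plane normal"))
}

# Orthonormal in-plane basis (e1, e2) with e1 x e2 = normal, so that
# counterclockwise in (e1, e2) coordinates means positive circulation about
# the normal. Deterministic for a given normal.
plane_basis <- function(normal) {
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3(ref, normal))
  e2 <- cross3(normal, e1)
  list(e1 = e1, e2 = e2)
}

# Signed polygon area (shoelace); positive for counterclockwise vertices.
polygon_signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Cross-section of a closed surface with a plane
#'
#' Intersects the plane with every triangle of the (watertight) surface and
#' chains the resulting segments into closed polygons expressed in 2-D
#' in-plane coordinates (mm), ordered counterclockwise about the plane
#' normal. Vertices lying numerically on the plane are perturbed to one side
#' by 1e-9 mm so the section is always topologically consistent.
#'
#' @param surface an `endocardial_surface` (closed).
#' @param plane `list(point =, normal =)`; the normal is normalized.
#' @return An object of class `cross_section`: `plane`, `basis` (the two
#'   in-plane unit vectors), `polygons` (list of k x 2 CCW matrices),
#'   `areas` (mm^2) and `area` (their sum).
#' @export
plane_cross_section <- function(surface, plane) {
  stopifnot(is_endocardial_surface(surface))
  plane <- as_plane(plane)
  V <- surface$vertices; F <- surface$faces
  s <- drop(sweep(V, 2, plane$point) %*% plane$normal)
  s[abs(s) < PLANE_EPS] <- PLANE_EPS
  pos <- s > 0
  fp <- matrix(pos[F], nrow(F), 3L)
  cut <- which(rowSums(fp) %in% c(1L, 2L))
  if (length(cut) == 0L) {
    stop_data("plane does not intersect the surface: empty cross-section")
  }

  # per cut face, the two edges whose endpoints straddle the plane
  edge_a <- matrix(0L, length(cut), 2L)
  edge_b <- matrix(0L, length(cut), 2L)
  for (r in seq_along(cut)) {
    f <- F[cut[r], ]
    odd <- which(fp[cut[r], ] == (sum(fp[cut[r], ]) == 1L))
    others <- setdiff(1:3, odd)
    edge_a[r, ] <- sort(c(f[odd], f[others[1]]))
    edge_b[r, ] <- sort(c(f[odd], f[others[2]]))
  }
  ekey <- function(e) paste(e[, 1], e[, 2])
  keys_a <- ekey(edge_a); keys_b <- ekey(edge_b)
  all_keys <- unique(c(keys_a, keys_b))
  edges <- unique(rbind(edge_a, edge_b))
  rownames(edges) <- ekey(edges)
  edges <- edges[all_keys, , drop = FALSE]

  # intersection point on each crossing edge
  i <- edges[, 1]; j <- edges[, 2]
  tpar <- s[i] / (s[i] - s[j])
  ipts <- V[i, , drop = FALSE] + (V[j, , drop = FALSE] - V[i, , drop = FALSE]) * tpar

  # each crossing edge is shared by exactly two cut faces: walk the cycles
  ia <- match(keys_a, all_keys); ib <- match(keys_b, all_keys)
  nbr <- matrix(NA_integer_, length(all_keys), 2L)
  slot <- rep(1L, length(all_keys))
  link <- function(u, v) {
    nbr[u, slot[u]] <<- v
    slot[u] <<- slot[u] + 1L
  }
  for (r in seq_along(cut)) {
    link(ia[r], ib[r]); link(ib[r], ia[r])
  }
  if (any(is.na(nbr))) {
    stop_data("cross-section segments do not close: surface is not watertight")
  }

  basis <- plane_basis(plane$normal)
  coords2 <- cbind(drop(sweep(ipts, 2, plane$point) %*% basis$e1),
                   drop(sweep(ipts, 2, plane$point) %*% basis$e2))
  visited <- logical(length(all_keys))
  polygons <- list()
  for (start in seq_along(all_keys)) {
    if (visited[start]) next
    loop <- integer(0)
    prev <- 0L; cur <- start
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nxt <- if (nbr[cur, 1] == prev) nbr[cur, 2] else nbr[cur, 1]
      prev <- cur; cur <- nxt
      if (cur == start) break
    }
    poly <- coords2[loop, , drop = FALSE]
    if (polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
    polygons[[length(polygons) + 1L]] <- poly
  }
  areas <- vapply(polygons, function(p) abs(polygon_signed_area(p)), numeric(1))
  structure(list(plane = plane, basis = basis, polygons = polygons,
                 areas = areas, area = sum(areas)),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("Cross-section: %d polygon(s), total area %.2f mm^2\n",
              length(x$polygons), x$area))
  invisible(x)
}

# --- 2-D polygon intersection (ear clipping + Sutherland-Hodgman) ---------

# Strictly-inside test of points against triangle (a, b, c), CCW.
points_strictly_inside_tri <- function(pts, a, b, c, eps = 1e-9) {
  cr <- function(p, q, r) (q[1] - p[1]) * (r[, 2] - p[2]) - (q[2] - p[2]) * (r[, 1] - p[1])
  cr(a, b, pts) > eps & cr(b, c, pts) > eps & cr(c, a, pts) > eps
}

# Ear-clipping triangulation of a simple CCW polygon; returns a list of
# 3 x 2 coordinate matrices. Falls back to clipping the most convex corner
# if numerical degeneracy leaves no strict ear.
triangulate_polygon <- function(p) {
  if (polygon_signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  idx <- seq_len(nrow(p))
  tris <- vector("list", max(0L, nrow(p) - 2L))
  nt <- 0L
  guard <- 0L
  while (length(idx) > 3L) {
    n <- length(idx)
    ear <- NA_integer_
    crosses <- numeric(n)
    for (k in seq_len(n)) {
      a <- p[idx[(k - 2L) %% n + 1L], ]
      b <- p[idx[k], ]
      c <- p[idx[k %% n + 1L], ]
      crosses[k] <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
      if (crosses[k] < -1e-9) next
      rest <- idx[-c((k - 2L) %% n + 1L, k, k %% n + 1L)]
      if (length(rest) == 0L ||
          !any(points_strictly_inside_tri(p[rest, , drop = FALSE], a, b, c))) {
        ear <- k
        break
      }
    }
    if (is.na(ear)) ear <- which.max(crosses)
    k <- ear
    a <- idx[(k - 2L) %% n + 1L]; b <- idx[k]; c <- idx[k %% n + 1L]
    nt <- nt + 1L
    tris[[nt]] <- p[c(a, b, c), , drop = FALSE]
    idx <- idx[-k]
    guard <- guard + 1L
    if (guard > 10000L) stop_data("polygon triangulation failed to terminate")
  }
  nt <- nt + 1L
  tris[[nt]] <- p[idx, , drop = FALSE]
  tris[seq_len(nt)]
}

# Sutherland-Hodgman clip of an arbitrary simple subject polygon against a
# convex CCW clip polygon; points on the boundary count as inside. The
# output's signed area equals the intersection area even when the subject is
# non-convex.
clip_polygon_convex <- function(subject, clip, eps = 1e-9) {
  out <- subject
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (nrow(out) < 3L) return(out[0, , drop = FALSE])
    a <- clip[k, ]; b <- clip[k %% nc + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    sdist <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    inside <- sdist >= -eps
    n <- nrow(out)
    nxt <- c(2:n, 1L)
    res <- matrix(numeric(0), 0L, 2L)
    for (i in seq_len(n)) {
      j <- nxt[i]
      if (inside[i]) {
        res <- rbind(res, out[i, ])
        if (!inside[j]) {
          t <- sdist[i] / (sdist[i] - sdist[j])
          res <- rbind(res, out[i, ] + t * (out[j, ] - out[i, ]))
        }
      } else if (inside[j]) {
        t <- sdist[i] / (sdist[i] - sdist[j])
        res <- rbind(res, out[i, ] + t * (out[j, ] - out[i, ]))
      }
    }
    out <- res
  }
  out
}

# Intersection area of two simple polygons: triangulate the first, clip the
# second against each (convex) triangle, sum the clipped areas.
polygon_intersection_area <- function(pa, pb) {
  if (polygon_signed_area(pa) < 0) pa <- pa[rev(seq_len(nrow(pa))), , drop = FALSE]
  if (polygon_signed_area(pb) < 0) pb <- pb[rev(seq_len(nrow(pb))), , drop = FALSE]
  total <- 0
  for (tri in triangulate_polygon(pa)) {
    if (abs(polygon_signed_area(tri)) < 1e-12) next
    if (polygon_signed_area(tri) < 0) tri <- tri[3:1, , drop = FALSE]
    clipped <- clip_polygon_convex(pb, tri)
    if (nrow(clipped) >= 3L) total <- total + abs(polygon_signed_area(clipped))
  }
  total
}

#' Dice coefficient of two surfaces in a common section plane
#'
#' Cross-sections both surfaces with the same plane and computes
#' `Dice = 2 |A intersect B| / (|A| + |B|)` on the resulting 2-D polygon
#' areas — the three-chamber-view overlap measure when the plane is the
#' three-chamber plane.
#'
#' @param surf_a,surf_b `endocardial_surface` objects in a common frame.
#' @param plane `list(point =, normal =)`.
#' @return Dice coefficient in \[0, 1\].
#' @export
three_chamber_dice <- function(surf_a, surf_b, plane) {
  sa <- plane_cross_section(surf_a, plane)
  sb <- plane_cross_section(surf_b, plane)
  inter <- 0
  for (pa in sa$polygons) {
    for (pb in sb$polygons) {
      inter <- inter + polygon_intersection_area(pa, pb)
    }
  }
  denom <- sa$area + sb$area
  if (denom <= 0) stop_data("degenerate cross-sections: zero total area")
  min(1, max(0, 2 * inter / denom))
}
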