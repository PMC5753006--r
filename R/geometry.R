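# Shared 3-D geometric primitives: rigid transforms, anatomical landmark
# frames, vector angles, plane projections. All lengths are millimeters in a
# right-handed world frame; angles are reported in degrees.

ORTHONORMALITY_TOL <- 1e-9
# Minimum apex/mitral/outflow triangle area (mm^2) below which anatomical
# frame construction is refused as degenerate.
LANDMARK_AREA_TOL <- 1.0

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("lvfuse_degenerate_error", "lvfuse_error"),
                      call = sys.call(-1)))
}

stop_data <- function(msg) {
  stop(errorCondition(msg, class = c("lvfuse_data_error", "lvfuse_error"),
                      call = sys.call(-1)))
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop_data(sprintf("%s must be 3 finite coordinates (mm)", what))
  }
  p
}

as_points_matrix <- function(pts) {
  if (is.null(dim(pts))) {
    pts <- matrix(as.numeric(pts), ncol = 3L, byrow = TRUE)
  }
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop_data("points must be an n x 3 matrix")
  if (!all(is.finite(pts))) stop_data("points contain non-finite coordinates")
  pts
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) stop_degenerate(sprintf("%s has (near-)zero length", what))
  v / n
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Construct a rigid transform
#'
#' A rigid (proper Euclidean) transform `p -> R p + t`: a 3x3 rotation matrix
#' plus a translation in mm. Rotation matrices are checked for orthonormality
#' and `det(R) = +1` (no scaling, no reflection).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric, mm.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' T1 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(10, 0, 0))
#' apply_transform(T1, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  translation <- as_point3(translation, "translation")
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    stop_data("rotation must be a finite 3x3 matrix")
  }
  if (max(abs(crossprod(rotation) - diag(3))) >= ORTHONORMALITY_TOL) {
    stop_data("rotation matrix is not orthonormal")
  }
  if (det(rotation) < 0) {
    stop_data("rotation matrix is a reflection (det = -1); rigid transforms must be proper")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (mm):\n")
  cat("  rotation angle:", format(rotation_angle(x$rotation), digits = 6), "deg\n")
  cat("  translation:   ", paste(format(x$translation, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Identity rigid transform
#' @return A `rigid_transform` that leaves every point fixed.
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle_deg` degrees about `axis` (normalized
#' internally), right-hand rule.
#'
#' @param axis length-3 numeric, any nonzero vector.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  k <- unitize(as_point3(axis, "axis"), "rotation axis")
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation angle (deg) of a rotation matrix, numerically stable near 0:
# atan2 of the axial (skew) part against trace instead of a bare acos.
rotation_angle <- function(R) {
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  atan2(vnorm(ax), (sum(diag(R)) - 1) / 2) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param pts a length-3 vector or an n x 3 matrix of points (mm).
#' @return Transformed points with the same shape as the input.
#' @export
apply_transform <- function(transform, pts) {
  stopifnot(is_rigid_transform(transform))
  single <- is.null(dim(pts))
  m <- as_points_matrix(pts)
  out <- m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3L, byrow = TRUE)
  if (single && nrow(out) == 1L) drop(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform applying `t1` first, then
#' `t2`: `apply(compose(t2, t1), p) == apply(t2, apply(t1, p))`.
#'
#' @param t2,t1 `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  stopifnot(is_rigid_transform(t2), is_rigid_transform(t1))
  rigid_transform(t2$rotation %*% t1$rotation,
                  drop(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(is_rigid_transform(transform))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, drop(-Rt %*% transform$translation))
}

#' Rotation and translation difference between two rigid transforms
#'
#' Used to compare an estimated registration against a ground truth:
#' the residual rotation angle of `R1 R2^T` and the Euclidean distance
#' between the translation vectors.
#'
#' @param t1,t2 `rigid_transform` objects.
#' @return list with `rotation_deg` and `translation_mm`.
#' @export
transform_difference <- function(t1, t2) {
  stopifnot(is_rigid_transform(t1), is_rigid_transform(t2))
  list(rotation_deg = rotation_angle(t1$rotation %*% t(t2$rotation)),
       translation_mm = vnorm(t1$translation - t2$translation))
}

#' Angle between two vectors
#'
#' @param u,v length-3 numeric vectors, nonzero.
#' @return Angle in degrees, in \[0, 180\].
#' @export
angle_between <- function(u, v) {
  u <- as_point3(u, "u"); v <- as_point3(v, "v")
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) stop_degenerate("angle_between: zero-length vector")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Project a vector onto a plane
#'
#' Removes the component of `v` along the unit normal `n`: `v - (v.n) n`.
#'
#' @param v length-3 numeric vector.
#' @param n unit normal of the plane.
#' @return The in-plane component of `v`.
#' @export
project_onto_plane <- function(v, n) {
  v <- as_point3(v, "v"); n <- as_point3(n, "n")
  if (abs(vnorm(n) - 1) > 1e-8) stop_data("plane normal must be a unit vector")
  v - sum(v * n) * n
}

#' Anatomical landmark triplet for one modality
#'
#' The three segmented LV landmarks used by every registration method:
#' endocardial apex, mitral valve center, and outflow tract / aortic valve
#' center, each in mm.
#'
#' @param apex,mitral_center,outflow_tract length-3 numeric points (mm).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(apex, mitral_center, outflow_tract) {
  lm <- structure(list(apex = as_point3(apex, "apex"),
                       mitral_center = as_point3(mitral_center, "mitral_center"),
                       outflow_tract = as_point3(outflow_tract, "outflow_tract")),
                  class = "landmark_set")
  d <- stats::dist(landmark_matrix(lm))
  if (any(d < 1e-9)) stop_degenerate("landmarks must be three distinct points")
  lm
}

is_landmark_set <- function(x) inherits(x, "landmark_set")

# 3 x 3 matrix, rows apex / mitral_center / outflow_tract.
landmark_matrix <- function(lm) {
  stopifnot(is_landmark_set(lm))
  rbind(apex = lm$apex, mitral_center = lm$mitral_center,
        outflow_tract = lm$outflow_tract)
}

landmark_triangle_area <- function(lm) {
  vnorm(cross3(lm$apex - lm$mitral_center, lm$outflow_tract - lm$mitral_center)) / 2
}

#' Transform all landmarks of a set
#' @param transform a `rigid_transform`.
#' @param lm a `landmark_set`.
#' @return The transformed `landmark_set`.
#' @export
transform_landmarks <- function(transform, lm) {
  stopifnot(is_landmark_set(lm))
  landmark_set(apply_transform(transform, lm$apex),
               apply_transform(transform, lm$mitral_center),
               apply_transform(transform, lm$outflow_tract))
}

#' Build the anatomical frame of a landmark set
#'
#' Orthonormal right-handed frame anchored at the mitral valve center:
#' `long_axis` points from the mitral center to the apex; `plane_normal` is
#' the normal of the apex/mitral/outflow (three-chamber) plane, oriented as
#' `long_axis x (outflow - mitral)`; `in_plane = plane_normal x long_axis`
#' completes the triad and points toward the outflow-tract side.
#'
#' @param lm a `landmark_set`. The landmark triangle must have area above
#'   1 mm^2, otherwise the frame is degenerate and an error is raised.
#' @return list with `origin`, `long_axis`, `plane_normal`, `in_plane`.
#' @export
build_frame <- function(lm) {
  stopifnot(is_landmark_set(lm))
  if (landmark_triangle_area(lm) <= LANDMARK_AREA_TOL) {
    stop_degenerate("landmarks are (near-)collinear: anatomical frame is undefined")
  }
  long_axis <- unitize(lm$apex - lm$mitral_center, "long axis")
  plane_normal <- unitize(cross3(long_axis, lm$outflow_tract - lm$mitral_center),
                          "three-chamber plane normal")
  in_plane <- cross3(plane_normal, long_axis)
  list(origin = lm$mitral_center, long_axis = long_axis,
       plane_normal = plane_normal, in_plane = in_plane)
}

# Rigid transform mapping canonical coordinates into a frame:
# columns of R are the frame axes; origin is the frame origin.
frame_as_transform <- function(frame) {
  rigid_transform(cbind(frame$long_axis, frame$in_plane, frame$plane_normal),
                  frame$origin)
}
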