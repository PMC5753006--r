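# Registration-quality measures for one fused dataset pair and the
# observer-variability measures on repeated segmentations. Geometry is in mm
# internally; reports use cm and degrees, matching clinical convention.

MM_PER_CM <- 10

quality_measures <- c("apex_distance", "mitral_center_distance",
                      "aortic_center_distance", "long_axis_angle",
                      "transverse_plane_angle", "mean_point_to_point_distance",
                      "three_chamber_dice")

quality_measure_labels <- c(
  apex_distance = "Apex distance (cm)",
  mitral_center_distance = "Mitral center distance (cm)",
  aortic_center_distance = "Aortic center distance (cm)",
  long_axis_angle = "Long-axis angle (deg)",
  transverse_plane_angle = "Transverse-plane angle (deg)",
  mean_point_to_point_distance = "Mean point-to-point distance (cm)",
  three_chamber_dice = "Three-chamber Dice's coefficient"
)

new_quality_report <- function(vals) {
  stopifnot(setequal(names(vals), quality_measures))
  vals <- vals[quality_measures]
  dists <- vals[c(1:3, 6)]
  if (any(dists < 0)) stop_data("distances must be >= 0")
  if (vals["long_axis_angle"] < 0 || vals["long_axis_angle"] > 180 ||
      vals["transverse_plane_angle"] < 0 || vals["transverse_plane_angle"] > 180) {
    stop_data("angles must lie in [0, 180] degrees")
  }
  if (vals["three_chamber_dice"] < 0 || vals["three_chamber_dice"] > 1) {
    stop_data("Dice coefficient must lie in [0, 1]")
  }
  structure(as.list(vals), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Registration quality report:\n")
  for (m in quality_measures) {
    cat(sprintf("  %-34s %.1f\n", quality_measure_labels[[m]],
                round(x[[m]], 1)))
  }
  invisible(x)
}

#' @export
as.data.frame.quality_report <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Inter-modality landmark distances
#'
#' Euclidean distances between corresponding landmarks of the fixed
#' (reference) set and an already-registered moving set: apex distance,
#' mitral center distance and aortic/outflow center distance, in cm.
#'
#' @param ref fixed `landmark_set` (mm).
#' @param moved moving `landmark_set`, already expressed in the reference
#'   frame (apply the registration transform first).
#' @return Named numeric vector `apex_distance`, `mitral_center_distance`,
#'   `aortic_center_distance` (cm).
#' @export
landmark_distances <- function(ref, moved) {
  stopifnot(is_landmark_set(ref), is_landmark_set(moved))
  c(apex_distance = vnorm(ref$apex - moved$apex),
    mitral_center_distance = vnorm(ref$mitral_center - moved$mitral_center),
    aortic_center_distance = vnorm(ref$outflow_tract - moved$outflow_tract)) / MM_PER_CM
}

#' Long-axis angle between two registered datasets
#'
#' Angle between the two LV long axes (mitral valve center to endocardial
#' apex), in degrees.
#'
#' @inheritParams landmark_distances
#' @return Angle in degrees.
#' @export
long_axis_angle <- function(ref, moved) {
  stopifnot(is_landmark_set(ref), is_landmark_set(moved))
  angle_between(ref$apex - ref$mitral_center, moved$apex - moved$mitral_center)
}

#' Transverse-plane angle between two registered datasets
#'
#' Rotation discrepancy about the long axis: an average long axis is formed
#' from the two unit long-axis vectors; both outflow/aortic centers, taken
#' relative to the midpoint of the two mitral centers, are projected onto
#' the plane orthogonal to that average axis, and the angle between the
#' projections is returned (degrees).
#'
#' @inheritParams landmark_distances
#' @return Angle in degrees.
#' @export
transverse_plane_angle <- function(ref, moved) {
  stopifnot(is_landmark_set(ref), is_landmark_set(moved))
  u1 <- unitize(ref$apex - ref$mitral_center, "reference long axis")
  u2 <- unitize(moved$apex - moved$mitral_center, "moving long axis")
  d <- unitize(u1 + u2, "average long axis")
  anchor <- (ref$mitral_center + moved$mitral_center) / 2
  u <- project_onto_plane(ref$outflow_tract - anchor, d)
  v <- project_onto_plane(moved$outflow_tract - anchor, d)
  if (vnorm(u) < 1e-6 || vnorm(v) < 1e-6) {
    stop_degenerate("outflow center lies on the long axis: transverse-plane angle undefined")
  }
  angle_between(u, v)
}

#' Mean point-to-surface distance
#'
#' Mean over all moving-surface points of the distance to the closest point
#' on the fixed triangulated surface (directed, moving -> fixed), in cm.
#'
#' @param src_pts n x 3 matrix of points, or an `endocardial_surface`
#'   (already expressed in the fixed frame).
#' @param dst fixed `endocardial_surface`.
#' @return Mean distance in cm.
#' @export
mean_point_to_surface_distance <- function(src_pts, dst) {
  stopifnot(is_endocardial_surface(dst))
  if (is_endocardial_surface(src_pts)) src_pts <- src_pts$vertices
  src_pts <- as_points_matrix(src_pts)
  if (nrow(src_pts) == 0L) stop_data("no source points")
  mean(nearest_surface_points(src_pts, dst)$distance) / MM_PER_CM
}

#' Evaluate the quality of a registration
#'
#' Applies the registration transform to the moving (echo) dataset and
#' computes the seven quality measures against the fixed (ccta) dataset:
#' three landmark distances, long-axis angle, transverse-plane angle, mean
#' point-to-surface distance, and the Dice coefficient of the two surface
#' cross-sections in the section plane (by default the fixed dataset's own
#' three-chamber plane from [build_frame()]).
#'
#' @param ccta fixed `lv_dataset`.
#' @param echo moving `lv_dataset`.
#' @param transform `rigid_transform` mapping echo into the ccta frame.
#' @param plane optional `list(point =, normal =)` section plane; default is
#'   the fixed dataset's three-chamber plane.
#' @return A `quality_report` (distances cm, angles deg, Dice unitless).
#' @export
evaluate_registration <- function(ccta, echo, transform, plane = NULL) {
  stopifnot(is_lv_dataset(ccta), is_lv_dataset(echo),
            is_rigid_transform(transform))
  if (is.null(plane)) {
    fr <- build_frame(ccta$landmarks)
    plane <- list(point = fr$origin, normal = fr$plane_normal)
  }
  moved <- transform_dataset(transform, echo)
  ld <- landmark_distances(ccta$landmarks, moved$landmarks)
  new_quality_report(c(
    ld,
    long_axis_angle = long_axis_angle(ccta$landmarks, moved$landmarks),
    transverse_plane_angle = transverse_plane_angle(ccta$landmarks, moved$landmarks),
    mean_point_to_point_distance =
      mean_point_to_surface_distance(moved$surface, ccta$surface),
    three_chamber_dice = three_chamber_dice(ccta$surface, moved$surface, plane)
  ))
}

#' Observer variability between two registrations
#'
#' Compares the registrations obtained from an original segmentation
#' (`transform`, landmarks `lm`) and a repeated segmentation
#' (`transform_prime`, landmarks `lm_prime`): distances between
#' correspondingly transformed landmarks, the angle between the two
#' transformed long axes, and the transverse-plane angle of the two
#' transformed outflow points about the fixed reference long axis (from the
#' reference mitral center to the reference apex).
#'
#' @param transform,transform_prime `rigid_transform`s from the original and
#'   repeated segmentation.
#' @param lm,lm_prime the corresponding moving-modality `landmark_set`s.
#' @param ref_mitral,ref_apex reference (fixed-modality) mitral valve center
#'   and apex defining the reference long axis (mm).
#' @return list of class `variability_report`: `apex_distance`,
#'   `mitral_center_distance`, `outflow_center_distance` (cm),
#'   `long_axis_angle`, `transverse_plane_angle` (deg).
#' @export
observer_variability <- function(transform, transform_prime, lm, lm_prime,
                                 ref_mitral, ref_apex) {
  stopifnot(is_rigid_transform(transform), is_rigid_transform(transform_prime),
            is_landmark_set(lm), is_landmark_set(lm_prime))
  ref_mitral <- as_point3(ref_mitral, "ref_mitral")
  ref_apex <- as_point3(ref_apex, "ref_apex")
  a <- transform_landmarks(transform, lm)
  b <- transform_landmarks(transform_prime, lm_prime)
  d <- unitize(ref_apex - ref_mitral, "reference long axis")
  u <- project_onto_plane(a$outflow_tract - ref_mitral, d)
  v <- project_onto_plane(b$outflow_tract - ref_mitral, d)
  if (vnorm(u) < 1e-6 || vnorm(v) < 1e-6) {
    stop_degenerate("outflow center lies on the reference axis: transverse-plane angle undefined")
  }
  structure(list(
    apex_distance = vnorm(a$apex - b$apex) / MM_PER_CM,
    mitral_center_distance = vnorm(a$mitral_center - b$mitral_center) / MM_PER_CM,
    outflow_center_distance = vnorm(a$outflow_tract - b$outflow_tract) / MM_PER_CM,
    long_axis_angle = angle_between(a$apex - a$mitral_center,
                                    b$apex - b$mitral_center),
    transverse_plane_angle = angle_between(u, v)
  ), class = "variability_report")
}

#' @export
as.data.frame.variability_report <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' @export
print.variability_report <- function(x, ...) {
  cat("Observer variability report:\n")
  lab <- c(apex_distance = "Apex distance (cm)",
           mitral_center_distance = "Mitral center distance (cm)",
           outflow_center_distance = "Outflow center distance (cm)",
           long_axis_angle = "Long-axis angle (deg)",
           transverse_plane_angle = "Transverse-plane angle (deg)")
  for (m in names(lab)) cat(sprintf("  %-34s %.1f\n", lab[[m]], round(x[[m]], 1)))
  invisible(x)
}
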