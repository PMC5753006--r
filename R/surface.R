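# Triangulated endocardial surface container and basic mesh queries.

#' Triangulated endocardial surface
#'
#' The segmented LV endocardial surface of one modality: an n x 3 vertex
#' matrix (mm) plus an m x 3 matrix of 1-based triangle vertex indices.
#' Phantom surfaces generated by this package are closed (watertight), which
#' plane cross-sections rely on.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices (triangles).
#' @return An object of class `endocardial_surface`.
#' @export
endocardial_surface <- function(vertices, faces) {
  vertices <- as_points_matrix(vertices)
  faces <- as.matrix(faces)
  if (nrow(vertices) < 3L) stop_data("surface needs at least 3 vertices")
  if (ncol(faces) != 3L || nrow(faces) < 1L) {
    stop_data("faces must be an m x 3 matrix of triangle vertex indices")
  }
  if (any(faces != round(faces)) || any(faces < 1L) || any(faces > nrow(vertices))) {
    stop_data("face indices must be integers in 1..n_vertices")
  }
  storage.mode(faces) <- "integer"
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3])) {
    stop_data("degenerate face: repeated vertex index within a triangle")
  }
  structure(list(vertices = vertices, faces = faces),
            class = "endocardial_surface")
}

is_endocardial_surface <- function(x) inherits(x, "endocardial_surface")

#' @export
print.endocardial_surface <- function(x, ...) {
  cat(sprintf("Endocardial surface: %d vertices, %d triangles (mm)\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Apply a rigid transform to a surface
#' @param transform a `rigid_transform`.
#' @param surface an `endocardial_surface`.
#' @return The transformed surface (same connectivity).
#' @export
transform_surface <- function(transform, surface) {
  stopifnot(is_endocardial_surface(surface))
  endocardial_surface(apply_transform(transform, surface$vertices), surface$faces)
}

#' Check that a surface is watertight
#'
#' A closed triangulated surface has every undirected edge shared by exactly
#' two triangles.
#'
#' @param surface an `endocardial_surface`.
#' @return TRUE/FALSE.
#' @export
is_watertight <- function(surface) {
  stopifnot(is_endocardial_surface(surface))
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Segmented LV dataset for one modality
#'
#' Bundles what the segmentation step produces for each modality: the
#' endocardial surface and the three anatomical landmarks.
#'
#' @param landmarks a `landmark_set`.
#' @param surface an `endocardial_surface`.
#' @param modality optional label, e.g. "ccta" or "echo".
#' @return An object of class `lv_dataset`.
#' @export
lv_dataset <- function(landmarks, surface, modality = NA_character_) {
  stopifnot(is_landmark_set(landmarks), is_endocardial_surface(surface))
  structure(list(landmarks = landmarks, surface = surface, modality = modality),
            class = "lv_dataset")
}

is_lv_dataset <- function(x) inherits(x, "lv_dataset")

#' Apply a rigid transform to a whole dataset
#' @param transform a `rigid_transform`.
#' @param dataset an `lv_dataset`.
#' @return The transformed dataset.
#' @export
transform_dataset <- function(transform, dataset) {
  stopifnot(is_lv_dataset(dataset))
  lv_dataset(transform_landmarks(transform, dataset$landmarks),
             transform_surface(transform, dataset$surface),
             dataset$modality)
}
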