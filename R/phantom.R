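# Synthetic LV phantom: a closed icosphere-derived semi-ellipsoidal
# endocardial surface with flattened basal cap, anatomical landmarks, and
# paired two-modality datasets with a known ground-truth rigid transform.
# Emulates what semiautomatic LV segmentation produces for each modality so
# the registration methods and metrics are testable without clinical data.

#' Phantom generation parameters
#'
#' @param subdivision_level icosphere subdivision level (>= 0). Level 3
#'   gives the 642-vertex / 1280-triangle closed surface matching the point
#'   clouds the registration methods operate on.
#' @param long_axis_length apex depth below the mitral (base) plane, mm.
#' @param base_radius basal cap radius, mm.
#' @param wall_shape_exponent superellipse exponent of the wall profile;
#'   2 = semi-ellipsoid (default), larger values bulge toward a box.
#' @param noise_sd per-vertex isotropic Gaussian noise on the second
#'   modality's surface, mm.
#' @param shape_mismatch length-3 per-axis scale factors (x, y, z) applied to
#'   the second modality about the surface centroid, emulating a true
#'   inter-modality LV shape difference; each in (0.5, 2).
#' @param landmark_jitter_sd isotropic Gaussian jitter on the second
#'   modality's landmarks, mm.
#' @param rotation_range max ground-truth rotation angle, degrees.
#' @param translation_range max ground-truth translation magnitude, mm.
#' @param seed integer seed making the pair fully reproducible.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(subdivision_level = 3L,
                           long_axis_length = 80,
                           base_radius = 25,
                           wall_shape_exponent = 2,
                           noise_sd = 0,
                           shape_mismatch = c(1, 1, 1),
                           landmark_jitter_sd = 0,
                           rotation_range = 30,
                           translation_range = 20,
                           seed = 1L) {
  subdivision_level <- as.integer(subdivision_level)
  shape_mismatch <- as.numeric(shape_mismatch)
  if (length(shape_mismatch) == 1L) shape_mismatch <- rep(shape_mismatch, 3L)
  if (subdivision_level < 0L) stop_data("subdivision_level must be >= 0")
  if (long_axis_length <= 0 || base_radius <= 0 || wall_shape_exponent <= 0) {
    stop_data("long_axis_length, base_radius and wall_shape_exponent must be > 0")
  }
  if (noise_sd < 0 || landmark_jitter_sd < 0) {
    stop_data("noise/jitter standard deviations must be >= 0")
  }
  if (length(shape_mismatch) != 3L || any(shape_mismatch <= 0.5) ||
      any(shape_mismatch >= 2)) {
    stop_data("shape_mismatch must be 3 per-axis scale factors in (0.5, 2)")
  }
  if (rotation_range < 0 || translation_range < 0) {
    stop_data("rotation_range and translation_range must be >= 0")
  }
  structure(list(subdivision_level = subdivision_level,
                 long_axis_length = long_axis_length,
                 base_radius = base_radius,
                 wall_shape_exponent = wall_shape_exponent,
                 noise_sd = noise_sd,
                 shape_mismatch = shape_mismatch,
                 landmark_jitter_sd = landmark_jitter_sd,
                 rotation_range = rotation_range,
                 translation_range = translation_range,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Run code with a deterministic local RNG state, restoring the caller's
# stream afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Unit icosphere mesh
#'
#' Icosahedron subdivided `level` times with vertices pushed onto the unit
#' sphere. Oriented so that two antipodal mesh vertices sit exactly at the
#' poles (0, 0, +-1), which the LV mapping relies on. Vertex/face counts
#' follow closed icosphere combinatorics: V = 10 * 4^level + 2,
#' F = 20 * 4^level.
#'
#' @param level subdivision level (>= 0).
#' @return list with `vertices` and `faces`.
#' @export
icosphere <- function(level = 3L) {
  level <- as.integer(level)
  if (level < 0L) stop_data("subdivision level must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  V <- V / sqrt(1 + phi^2)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  # rotate vertex 6 = (0, 1, phi)/|.| to the +z pole (rotation about x)
  a <- V[6, 2]; b <- V[6, 3]
  Rx <- matrix(c(1, 0, 0, 0, b, a, 0, -a, b), 3, 3)
  V <- V %*% t(Rx)
  for (l in seq_len(level)) {
    nv <- nrow(V)
    edge_mid <- new.env(hash = TRUE, parent = emptyenv())
    verts <- vector("list", 0)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- edge_mid[[key]]
      if (is.null(idx)) {
        m <- (V[i, ] + V[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        verts[[length(verts) + 1L]] <<- m
        idx <- nv + length(verts)
        edge_mid[[key]] <- idx
      }
      idx
    }
    newF <- matrix(0L, nrow(F) * 4L, 3L)
    for (f in seq_len(nrow(F))) {
      i <- F[f, 1]; j <- F[f, 2]; k <- F[f, 3]
      ij <- midpoint(i, j); jk <- midpoint(j, k); ki <- midpoint(k, i)
      newF[(f - 1L) * 4L + 1:4, ] <- rbind(
        c(i, ij, ki), c(j, jk, ij), c(k, ki, jk), c(ij, jk, ki))
    }
    V <- rbind(V, do.call(rbind, verts))
    F <- newF
  }
  list(vertices = V, faces = F)
}

#' Generate the phantom LV endocardial surface and landmarks
#'
#' Maps a unit icosphere to an idealized LV endocardium: the lower hemisphere
#' becomes a semi-superellipsoidal wall (apex at `(0, 0, -long_axis_length)`),
#' the upper hemisphere is flattened onto the basal plane z = 0, yielding a
#' closed (watertight) surface with a capped base. Landmarks: apex = the apex
#' pole vertex; mitral valve center = center of the basal cap (a mesh
#' vertex); outflow tract = the fixed point `(base_radius, 0, 0)` on the
#' basal rim (the phantom's anatomical +x direction).
#'
#' @param params a [phantom_params()] object.
#' @return An `lv_dataset` (surface + landmarks, modality unset).
#' @export
generate_lv_surface <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  ico <- icosphere(params$subdivision_level)
  V <- ico$vertices
  R <- params$base_radius
  L <- params$long_axis_length
  e <- 2 / params$wall_shape_exponent
  z <- V[, 3]
  rho <- sqrt(pmax(0, 1 - z^2))
  out <- matrix(0, nrow(V), 3L)
  up <- z > 0
  # basal cap: keep xy position, drop to z = 0 (pole -> cap center)
  out[up, 1:2] <- V[up, 1:2] * R
  # wall: superellipse profile r = R cos(phi)^(2/n), depth = L sin(phi)^(2/n)
  lo <- !up
  s <- -z[lo]                      # sin(phi), in [0, 1]
  r <- R * rho[lo]^e
  dirx <- ifelse(rho[lo] > 1e-12, V[lo, 1] / rho[lo], 0)
  diry <- ifelse(rho[lo] > 1e-12, V[lo, 2] / rho[lo], 0)
  out[lo, 1] <- dirx * r
  out[lo, 2] <- diry * r
  out[lo, 3] <- -L * s^e
  surface <- endocardial_surface(out, ico$faces)
  lm <- landmark_set(apex = c(0, 0, -L), mitral_center = c(0, 0, 0),
                     outflow_tract = c(R, 0, 0))
  lv_dataset(lm, surface)
}

scale_about <- function(pts, center, factors) {
  sweep(sweep(sweep(as_points_matrix(pts), 2, center), 2, factors, `*`), 2, center, `+`)
}

#' Generate a paired two-modality phantom with known ground truth
#'
#' The first (reference, "ccta") dataset is the clean phantom surface. The
#' second ("echo") dataset is the same geometry with per-axis
#' `shape_mismatch` scaling about the surface centroid, per-vertex Gaussian
#' surface noise, landmark jitter, and finally moved out of the reference
#' frame by the inverse of a randomly sampled rigid transform. That sampled
#' transform, mapping echo coordinates back into the ccta frame, is returned
#' as `ground_truth`. With zero noise, zero jitter and unit scale factors,
#' `apply_transform(ground_truth, echo points)` reproduces the ccta points
#' exactly. Fully reproducible from `params$seed` (draw order: ground-truth
#' transform, surface noise, landmark jitter).
#'
#' @param params a [phantom_params()] object.
#' @return list of class `phantom_pair` with `ccta`, `echo` (`lv_dataset`),
#'   `ground_truth` (`rigid_transform`, echo -> ccta) and `params`.
#' @export
make_phantom_pair <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  base <- generate_lv_surface(params)
  with_seed(params$seed, {
    gt <- random_rigid_transform(params$rotation_range, params$translation_range)
    centroid <- colMeans(base$surface$vertices)
    ev <- scale_about(base$surface$vertices, centroid, params$shape_mismatch)
    elm_mat <- scale_about(landmark_matrix(base$landmarks), centroid,
                           params$shape_mismatch)
    if (params$noise_sd > 0) {
      ev <- ev + matrix(stats::rnorm(length(ev), sd = params$noise_sd),
                        nrow(ev), 3L)
    }
    if (params$landmark_jitter_sd > 0) {
      elm_mat <- elm_mat + matrix(stats::rnorm(9, sd = params$landmark_jitter_sd), 3L, 3L)
    }
    inv <- invert_transform(gt)
    echo <- lv_dataset(
      transform_landmarks(inv, landmark_set(elm_mat[1, ], elm_mat[2, ], elm_mat[3, ])),
      transform_surface(inv, endocardial_surface(ev, base$surface$faces)),
      modality = "echo")
    structure(list(ccta = lv_dataset(base$landmarks, base$surface, "ccta"),
                   echo = echo, ground_truth = gt, params = params),
              class = "phantom_pair")
  })
}

#' Emulate a repeated segmentation of both modalities
#'
#' Returns landmark sets of both datasets re-jittered with isotropic Gaussian
#' noise, emulating the landmark variation a repeated (intra- or
#' inter-observer) semiautomatic segmentation would produce, for use with
#' [observer_variability()].
#'
#' @param pair a `phantom_pair`.
#' @param resegmentation_jitter_sd isotropic jitter, mm.
#' @param seed integer seed.
#' @return list with `ccta` and `echo` `landmark_set` objects.
#' @export
make_repeated_segmentation <- function(pair, resegmentation_jitter_sd, seed = 1L) {
  stopifnot(inherits(pair, "phantom_pair"), resegmentation_jitter_sd >= 0)
  with_seed(seed, {
    jit <- function(lm) {
      m <- landmark_matrix(lm) +
        matrix(stats::rnorm(9, sd = resegmentation_jitter_sd), 3L, 3L)
      landmark_set(m[1, ], m[2, ], m[3, ])
    }
    list(ccta = jit(pair$ccta$landmarks), echo = jit(pair$echo$landmarks))
  })
}
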