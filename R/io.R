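# File I/O: triangulated meshes (ASCII PLY, OBJ, VTK legacy polydata),
# landmark and transform interchange in JSON, and CSV report writers. The
# canonical unit is mm; landmark/transform files declare their units and cm
# values are converted on read.

surface_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (!ext %in% c("ply", "obj", "vtk")) {
    stop_data(sprintf("unsupported mesh format '.%s' (supported: .ply, .obj, .vtk)", ext))
  }
  ext
}

#' Read a triangulated surface mesh
#'
#' Supported formats (chosen by file extension): ASCII PLY, Wavefront OBJ,
#' and VTK legacy polydata (ASCII). Non-triangular faces are rejected rather
#' than silently triangulated.
#'
#' @param path mesh file path (`.ply`, `.obj` or `.vtk`).
#' @return An `endocardial_surface`.
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("mesh file not found: %s", path))
  switch(surface_format(path),
         ply = read_ply(path),
         obj = read_obj(path),
         vtk = read_vtk(path))
}

#' Write a triangulated surface mesh
#'
#' @param surface an `endocardial_surface`.
#' @param path output path; the extension selects the format (see
#'   [read_surface()]). Coordinates are written in mm at full double
#'   precision, so write/read round-trips are exact.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(is_endocardial_surface(surface))
  switch(surface_format(path),
         ply = write_ply(surface, path),
         obj = write_obj(surface, path),
         vtk = write_vtk(surface, path))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply") {
    stop_data(sprintf("%s: not a PLY file (missing 'ply' magic)", path))
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop_data(sprintf("%s: PLY header has no end_header", path))
  header <- trimws(lines[seq_len(end)])
  fmt <- grep("^format ", header, value = TRUE)
  if (!length(fmt) || !grepl("^format ascii", fmt[1])) {
    stop_data(sprintf("%s: only ASCII PLY is supported", path))
  }
  nv <- suppressWarnings(as.integer(sub("^element vertex ", "",
                                        grep("^element vertex ", header, value = TRUE)[1])))
  nf <- suppressWarnings(as.integer(sub("^element face ", "",
                                        grep("^element face ", header, value = TRUE)[1])))
  if (is.na(nv) || is.na(nf)) {
    stop_data(sprintf("%s: PLY header lacks vertex/face element counts", path))
  }
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop_data(sprintf("%s: truncated PLY body", path))
  vparts <- strsplit(trimws(body[seq_len(nv)]), "[[:space:]]+")
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  if (any(!is.finite(verts))) stop_data(sprintf("%s: non-numeric vertex data", path))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "[[:space:]]+")
  faces <- t(vapply(fparts, function(p) {
    cnt <- suppressWarnings(as.integer(p[1]))
    if (is.na(cnt) || cnt != 3L) {
      stop_data(sprintf("%s: non-triangular face (%s vertices); only triangle meshes are supported",
                        path, p[1]))
    }
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  endocardial_surface(verts, faces)
}

write_ply <- function(surface, path) {
  v <- surface$vertices; f <- surface$faces
  header <- c("ply", "format ascii 1.0", "comment units mm",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  vlines <- paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3]))
  flines <- paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, vlines, flines), path)
}

read_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines) || !length(flines)) {
    stop_data(sprintf("%s: OBJ file has no vertices or no faces", path))
  }
  verts <- t(vapply(strsplit(vlines, "[[:space:]]+"),
                    function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(verts))) stop_data(sprintf("%s: non-numeric vertex data", path))
  faces <- t(vapply(strsplit(flines, "[[:space:]]+"), function(p) {
    p <- p[-1]
    if (length(p) != 3L) {
      stop_data(sprintf("%s: non-triangular face (%d vertices); only triangle meshes are supported",
                        path, length(p)))
    }
    as.integer(sub("/.*$", "", p))
  }, integer(3)))
  endocardial_surface(verts, faces)
}

write_obj <- function(surface, path) {
  v <- surface$vertices; f <- surface$faces
  writeLines(c("# units mm",
               paste("v", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
               paste("f", f[, 1], f[, 2], f[, 3])), path)
}

read_vtk <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (!length(lines) || !grepl("^# vtk DataFile", lines[1])) {
    stop_data(sprintf("%s: not a VTK legacy file", path))
  }
  if (!any(grepl("^ASCII$", lines))) {
    stop_data(sprintf("%s: only ASCII VTK legacy files are supported", path))
  }
  if (!any(grepl("^DATASET POLYDATA", lines))) {
    stop_data(sprintf("%s: expected DATASET POLYDATA", path))
  }
  pts_at <- grep("^POINTS ", lines)
  poly_at <- grep("^POLYGONS ", lines)
  if (!length(pts_at) || !length(poly_at)) {
    stop_data(sprintf("%s: missing POINTS or POLYGONS section", path))
  }
  nv <- as.integer(strsplit(lines[pts_at[1]], "[[:space:]]+")[[1]][2])
  nums <- as.numeric(unlist(strsplit(
    paste(lines[(pts_at[1] + 1L):(poly_at[1] - 1L)], collapse = " "),
    "[[:space:]]+")))
  nums <- nums[!is.na(nums)]
  if (length(nums) != 3L * nv) stop_data(sprintf("%s: POINTS count mismatch", path))
  verts <- matrix(nums, ncol = 3L, byrow = TRUE)
  hdr <- as.integer(strsplit(lines[poly_at[1]], "[[:space:]]+")[[1]][2:3])
  nf <- hdr[1]
  fnums <- as.integer(unlist(strsplit(
    paste(lines[(poly_at[1] + 1L):length(lines)], collapse = " "),
    "[[:space:]]+")))
  fnums <- fnums[!is.na(fnums)]
  if (length(fnums) < hdr[2]) stop_data(sprintf("%s: POLYGONS data truncated", path))
  faces <- matrix(NA_integer_, nf, 3L)
  pos <- 1L
  for (r in seq_len(nf)) {
    cnt <- fnums[pos]
    if (is.na(cnt) || cnt != 3L) {
      stop_data(sprintf("%s: non-triangular polygon (%d vertices); only triangle meshes are supported",
                        path, cnt))
    }
    faces[r, ] <- fnums[pos + 1:3] + 1L
    pos <- pos + 4L
  }
  endocardial_surface(verts, faces)
}

write_vtk <- function(surface, path) {
  v <- surface$vertices; f <- surface$faces
  writeLines(c("# vtk DataFile Version 3.0",
               "LV endocardial surface (units mm)",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v)),
               paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
               sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)),
               paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)), path)
}

#' Read anatomical landmarks from JSON
#'
#' Expected schema: an object with keys `apex`, `mitral_center`,
#' `outflow_tract` (each `[x, y, z]`) and `units` (`"mm"` or `"cm"`; cm
#' values are converted to mm). Missing keys are fatal; unknown keys produce
#' a warning.
#'
#' @param path JSON file path.
#' @return A `landmark_set` (mm).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("landmark file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("apex", "mitral_center", "outflow_tract")
  for (k in need) {
    if (is.null(obj[[k]])) stop_data(sprintf("%s: missing landmark key '%s'", path, k))
    if (!is.numeric(obj[[k]]) || length(obj[[k]]) != 3L) {
      stop_data(sprintf("%s: landmark '%s' must be 3 numbers", path, k))
    }
  }
  units <- obj$units
  if (is.null(units)) stop_data(sprintf("%s: missing 'units' field", path))
  scale <- switch(as.character(units), mm = 1, cm = 10,
                  stop_data(sprintf("%s: unsupported units '%s' (use mm or cm)", path, units)))
  extra <- setdiff(names(obj), c(need, "units"))
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown keys: %s", path, paste(extra, collapse = ", ")))
  }
  landmark_set(obj$apex * scale, obj$mitral_center * scale, obj$outflow_tract * scale)
}

#' Write anatomical landmarks to JSON
#' @param lm a `landmark_set` (mm).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(is_landmark_set(lm))
  jsonlite::write_json(list(units = "mm", apex = lm$apex,
                            mitral_center = lm$mitral_center,
                            outflow_tract = lm$outflow_tract),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#'
#' Expected schema: `{"units": "mm", "matrix": [[...], ...]}` with a 4x4
#' row-major homogeneous matrix. Orthonormality and `det = +1` of the
#' rotation block are re-validated on read, so corrupted or reflecting
#' matrices are rejected.
#'
#' @param path JSON file path.
#' @return A `rigid_transform`.
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("transform file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  m <- obj$matrix
  if (is.null(m) || !is.matrix(m) || !all(dim(m) == c(4L, 4L))) {
    stop_data(sprintf("%s: 'matrix' must be a 4x4 homogeneous matrix", path))
  }
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9) {
    stop_data(sprintf("%s: bottom row of homogeneous matrix must be 0 0 0 1", path))
  }
  tryCatch(rigid_transform(m[1:3, 1:3], m[1:3, 4]),
           lvfuse_data_error = function(e) {
             stop_data(sprintf("%s: matrix is not a proper rigid transform (%s)",
                               path, conditionMessage(e)))
           })
}

#' Write a rigid transform to JSON
#' @param transform a `rigid_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  stopifnot(is_rigid_transform(transform))
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(units = "mm", matrix = m), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write a quality report as a one-row CSV
#'
#' Columns are `subject`, `method`, then the seven quality measures (machine
#' names matching [cohort_table()]).
#'
#' @param report a `quality_report`.
#' @param path output path.
#' @param subject,method labels recorded with the row.
#' @return `path`, invisibly.
#' @export
write_quality_csv <- function(report, path, subject = "subject", method = "method") {
  stopifnot(inherits(report, "quality_report"))
  df <- cbind(data.frame(subject = subject, method = method), as.data.frame(report))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a directory of quality-report CSVs into one cohort table
#' @param dir directory containing CSVs written by [write_quality_csv()].
#' @return combined data.frame.
#' @export
read_cohort_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop_data(sprintf("no CSV files found in %s", dir))
  do.call(rbind, lapply(files, utils::read.csv, stringsAsFactors = FALSE))
}
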