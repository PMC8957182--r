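#' Write an image sequence to disk
#'
#' Two containers are supported: `"png"` writes one PNG per frame plus a
#' JSON sidecar (`sequence.json`) with frame rate, pixel spacing and frame
#' times - portable but 8-bit quantised (intensities are rescaled to the
#' sequence maximum); `"rds"` writes a single lossless R data file.
#' Coordinates in all sidecars are 0-based (x = column, y = row),
#' displacements positive rightward/downward.
#'
#' @param seq An [image_sequence()].
#' @param path Output directory (png) or file path (rds).
#' @param format `"png"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_image_sequence <- function(seq, path, format = c("png", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "image_sequence"))
  if (format == "rds") {
    saveRDS(seq, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  peak <- max(vapply(seq$frames, max, numeric(1)), 1e-12)
  for (k in seq_along(seq$frames)) {
    png::writePNG(clamp(seq$frames[[k]] / peak, 0, 1),
                  file.path(path, sprintf("frame_%04d.png", k)))
  }
  sidecar <- list(n_frames = length(seq$frames),
                  frame_rate = seq$frame_rate,
                  pixel_spacing = seq$pixel_spacing,
                  intensity_scale = peak,
                  coordinate_convention = paste(
                    "0-based image coordinates; x = column, y = row;",
                    "displacement positive rightward/downward"))
  jsonlite::write_json(sidecar, file.path(path, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image sequence written by [write_image_sequence()]
#'
#' @param path Directory with `frame_*.png` + `sequence.json`, or an `.rds`
#'   file.
#' @return An [image_sequence()].
#' @export
read_image_sequence <- function(path) {
  if (!dir.exists(path)) {
    seq <- readRDS(path)
    stopifnot(inherits(seq, "image_sequence"))
    return(seq)
  }
  sidecar <- jsonlite::read_json(file.path(path, "sequence.json"),
                                 simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  frames <- lapply(files, function(f) {
    png::readPNG(f) * sidecar$intensity_scale
  })
  image_sequence(frames, sidecar$frame_rate, sidecar$pixel_spacing)
}

#' Write a strain curve as CSV (plus timing JSON)
#'
#' @param curve A [strain_curve()].
#' @param path CSV path; the timing is written next to it as
#'   `<path>.timing.json`.
#' @return `path`, invisibly.
#' @export
write_strain_curve <- function(curve, path) {
  stopifnot(inherits(curve, "strain_curve"))
  utils::write.csv(data.frame(time_s = curve$time,
                              strain_pct = curve$strain),
                   path, row.names = FALSE)
  write_timing(curve$timing, paste0(path, ".timing.json"))
  invisible(path)
}

#' Read a strain curve written by [write_strain_curve()]
#'
#' @param path CSV path (expects `<path>.timing.json` alongside, or pass
#'   `timing` explicitly).
#' @param timing Optional [cardiac_timing()] overriding the sidecar.
#' @return A [strain_curve()].
#' @export
read_strain_curve <- function(path, timing = NULL) {
  d <- utils::read.csv(path)
  if (is.null(timing)) timing <- read_timing(paste0(path, ".timing.json"))
  strain_curve(d$time_s, d$strain_pct, timing)
}

#' Write / read a displacement field
#'
#' The field's arrays are stored in a single compressed container (RDS,
#' gzip) with a JSON schema sidecar (`<path>.schema.json`) documenting the
#' array layout and the coordinate convention.
#'
#' @param field An [estimate_displacements()] result.
#' @param path Output file path (e.g. `field.rds`).
#' @return `path` (write) or a `displacement_field` (read).
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  saveRDS(field, path, compress = "gzip")
  d <- dim(field$dx)
  schema <- list(
    arrays = list(
      dx = "frame_pair x radial x longitudinal, px",
      dy = "frame_pair x radial x longitudinal, px",
      correlation = "peak normalized cross-correlation in [-1, 1]",
      valid = "logical; FALSE = in-filled from neighbours",
      positions = "frame x radial x longitudinal x (x, y), px"),
    dims = list(n_frame_pairs = d[1], n_radial = d[2],
                n_longitudinal = d[3]),
    frame_rate = field$frame_rate,
    coordinate_convention = paste(
      "0-based image coordinates; x = column, y = row;",
      "displacement positive rightward/downward"))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  field <- readRDS(path)
  stopifnot(inherits(field, "displacement_field"))
  field
}

#' Write / read valve-timing annotations as JSON
#'
#' @param timing A [cardiac_timing()].
#' @param path JSON file path.
#' @return `path` (write) or a [cardiac_timing()] (read).
#' @export
write_timing <- function(timing, path) {
  stopifnot(inherits(timing, "cardiac_timing"))
  jsonlite::write_json(unclass(timing), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timing
#' @export
read_timing <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cardiac_timing(heart_rate = x$heart_rate, mvc_time = x$mvc_time,
                 avc_time = x$avc_time, cycle_length = x$cycle_length,
                 source = x$source)
}

#' Write / read a segmentation polygon as JSON
#'
#' The polygon is a list of (x, y) pixel coordinates, 0-based.
#'
#' @param polygon n x 2 matrix of vertices.
#' @param path JSON file path.
#' @return `path` (write) or an n x 2 matrix (read).
#' @export
write_segmentation <- function(polygon, path) {
  jsonlite::write_json(list(vertices = unname(as.matrix(polygon)),
                            coordinate_convention = "0-based (x, y) pixels"),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.matrix(x$vertices)
}
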