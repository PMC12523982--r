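#' Calibrated phase image
#'
#' A 2-D raster of optical path difference (OPD, micrometres) together
#' with the optics metadata needed to interpret it physically, an
#' acquisition time and a well label. The raster is stored as a plain
#' numeric matrix; rows index x (image columns in micrometres run along
#' rows times `pixel_size`).
#'
#' @param opd numeric matrix of OPD values, micrometres. Must be at
#'   least 2 x 2 and finite.
#' @param optics an [optics_config()].
#' @param time_h acquisition time, hours (may be `NA`).
#' @param well_id well label (character, may be `NA`).
#' @return An object of class `phase_image` with fields `opd`,
#'   `optics`, `time_h`, `well_id`.
#' @export
phase_image <- function(opd, optics = optics_config(), time_h = NA_real_,
                        well_id = NA_character_) {
  stopifnot(is.matrix(opd), is.numeric(opd))
  if (nrow(opd) < 2L || ncol(opd) < 2L)
    stop("phase image raster must be at least 2 x 2 pixels")
  if (!all(is.finite(opd)))
    stop("phase image raster contains non-finite values")
  stopifnot(inherits(optics, "optics_config"))
  structure(list(opd = opd, optics = optics,
                 time_h = as.numeric(time_h),
                 well_id = as.character(well_id)),
            class = "phase_image")
}

#' @export
dim.phase_image <- function(x) dim(x$opd)

#' @export
as.matrix.phase_image <- function(x, ...) x$opd

#' @export
print.phase_image <- function(x, ...) {
  d <- dim(x$opd)
  cat(sprintf("phase_image: %d x %d px (%.0f x %.0f um), OPD range [%.4g, %.4g] um\n",
              d[1], d[2], d[1] * x$optics$pixel_size, d[2] * x$optics$pixel_size,
              min(x$opd), max(x$opd)))
  if (!is.na(x$time_h)) cat(sprintf("  time: %g h\n", x$time_h))
  if (!is.na(x$well_id)) cat(sprintf("  well: %s\n", x$well_id))
  invisible(x)
}

#' Image extent in micrometres
#' @param image a [phase_image()].
#' @return numeric length-2 vector, extent along each raster dimension, um.
#' @export
image_extent <- function(image) {
  stopifnot(inherits(image, "phase_image"))
  dim(image$opd) * image$optics$pixel_size
}

#' Write a raster to TIFF with a JSON metadata sidecar
#'
#' Rasters are written as single-channel 32-bit float TIFF. Because
#' the float TIFF writer stores values in \[0, 1\], values are divided
#' by a power-of-two scale factor chosen to cover the data range; the
#' factor is recorded in a JSON sidecar (`<path>.json`) along with any
#' supplied metadata, and is reapplied on reading. The sidecar written
#' for a [phase_image()] carries the full optics configuration, time
#' and well label, so a round trip is lossless to float precision.
#'
#' @param x a [phase_image()] or a plain numeric matrix (e.g. a
#'   fluorescence raster or a label map).
#' @param path output TIFF path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param metadata optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(x, path, metadata = list()) {
  if (inherits(x, "phase_image")) {
    metadata <- c(list(kind = "phase_opd_um", optics = unclass(x$optics)),
                  if (!is.na(x$time_h)) list(time_h = x$time_h),
                  if (!is.na(x$well_id)) list(well_id = x$well_id),
                  metadata)
    m <- x$opd
  } else {
    stopifnot(is.matrix(x), is.numeric(x))
    m <- x
  }
  if (min(m) < 0) stop("raster values must be nonnegative for TIFF export")
  mx <- max(m)
  scale <- if (mx <= 0) 1 else 2^ceiling(log2(mx + .Machine$double.eps))
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L, reduce = FALSE)
  metadata$tiff_scale <- scale
  jsonlite::write_json(metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a raster written by [write_phase_tiff()]
#'
#' @param path TIFF path. A sidecar `<path>.json` written by
#'   [write_phase_tiff()] is used to undo the storage scaling and, for
#'   phase images, to restore optics metadata.
#' @param optics optional [optics_config()] overriding the sidecar's.
#' @param radians if `TRUE`, pixel values are interpreted as phase in
#'   radians and converted to OPD via `opd_from_phase()`.
#' @return a [phase_image()] if the sidecar identifies one (or
#'   `optics` is given), otherwise a plain matrix.
#' @export
read_phase_tiff <- function(path, optics = NULL, radians = FALSE) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  if (!is.null(meta$tiff_scale)) m <- m * meta$tiff_scale
  if (is.null(optics) && !is.null(meta$optics))
    optics <- do.call(optics_config, meta$optics)
  if (is.null(optics)) return(m)
  if (radians) m <- opd_from_phase(m, optics)
  phase_image(m, optics,
              time_h = if (is.null(meta$time_h)) NA_real_ else meta$time_h,
              well_id = if (is.null(meta$well_id)) NA_character_ else meta$well_id)
}
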