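#' Per-cell morphology metrics from a phase image and label map
#'
#' Computes, per labelled object:
#'
#' * `area`: pixel count x pixel_size^2, um^2.
#' * `dry_mass`: `sum(OPD) * pixel_size^2 / alpha`, pg — integrated
#'   optical path difference converted through the specific
#'   refractive increment.
#' * `mean_optical_thickness`, `max_optical_thickness`: OPD statistics
#'   over object pixels, um.
#' * `sphericity`: the physical thickness map is
#'   `t = OPD / (object_ri - medium_ri)`; volume `V = sum(t) px^2`,
#'   upper-surface area `S = sum(sqrt(1 + |grad t|^2)) px^2`
#'   (central-difference gradient), and sphericity `2 pi r^2 / S`
#'   with `r = (3V / 2 pi)^(1/3)` — the curved surface of the
#'   equal-volume hemisphere over the measured upper surface, clipped
#'   to (0, 1] against discretisation overshoot. A hemispherical cell
#'   scores 1; flat spread cells score far lower. Note sphericity is
#'   not invariant to the assumed refractive contrast: V and S both
#'   derive from the same delta-n, which therefore must be fixed per
#'   study.
#' * `length_width_ratio`: major/minor axis of the area-moment
#'   equivalent ellipse of the binary footprint (second-order central
#'   moments with the pixel-extent correction), rotation invariant by
#'   construction. `NA` (flagged) when the minor axis degenerates.
#' * `centroid` (um, pixel-centre convention), `touches_border`,
#'   `unreliable` (objects of fewer than 4 pixels), `time_h`,
#'   `well_id`.
#'
#' @param image a [phase_image()].
#' @param labels a [label_map()] aligned to `image` (same dimensions).
#' @return data frame with one row per object (see above), of class
#'   `cell_records`.
#' @export
measure <- function(image, labels) {
  stopifnot(inherits(image, "phase_image"), inherits(labels, "label_map"))
  if (!all(dim(image$opd) == dim(labels$labels)))
    stop(sprintf("image (%s) and label map (%s) dimensions differ",
                 paste(dim(image$opd), collapse = "x"),
                 paste(dim(labels$labels), collapse = "x")))
  px <- image$optics$pixel_size
  if (abs(px - labels$pixel_size) > 1e-12)
    stop("image and label map disagree on pixel size")
  lab <- labels$labels
  n <- max(lab)
  if (n == 0) return(.empty_records())
  opd <- image$opd
  dn <- delta_ri(image$optics)
  t <- opd / dn
  nr <- nrow(t); nc <- ncol(t)
  # central-difference gradient with zero padding (cells fall to zero
  # OPD at their rim, so the padded value is the physical continuation)
  padr <- rbind(0, t, 0); padc <- cbind(0, t, 0)
  gx <- (padr[3:(nr + 2), ] - padr[1:nr, ]) / (2 * px)
  gy <- (padc[, 3:(nc + 2)] - padc[, 1:nc]) / (2 * px)
  surf_el <- sqrt(1 + gx^2 + gy^2)
  sel <- which(lab > 0L)
  ij <- arrayInd(sel, dim(lab))
  dt <- data.table::data.table(
    id = lab[sel],
    opd = opd[sel],
    el = surf_el[sel],
    x = (ij[, 1] - 0.5) * px,
    y = (ij[, 2] - 0.5) * px,
    border = ij[, 1] == 1L | ij[, 1] == nr | ij[, 2] == 1L | ij[, 2] == nc)
  px2 <- px^2
  alpha <- image$optics$alpha
  agg <- dt[, list(
    n_px = .N,
    area = .N * px2,
    dry_mass = sum(opd) * px2 / alpha,
    mean_ot = mean(opd),
    max_ot = max(opd),
    volume = sum(opd) / dn * px2,
    surface = sum(el) * px2,
    cx = mean(x), cy = mean(y),
    sxx = mean(x^2) - mean(x)^2 + px2 / 12,
    syy = mean(y^2) - mean(y)^2 + px2 / 12,
    sxy = mean(x * y) - mean(x) * mean(y),
    touches_border = any(border)), by = "id"]
  data.table::setorder(agg, id)
  r_eq <- (3 * pmax(agg$volume, 0) / (2 * pi))^(1 / 3)
  sph <- 2 * pi * r_eq^2 / agg$surface
  sph <- pmin(pmax(sph, .Machine$double.eps), 1)
  tr <- (agg$sxx + agg$syy) / 2
  det <- sqrt(pmax(((agg$sxx - agg$syy) / 2)^2 + agg$sxy^2, 0))
  l1 <- tr + det; l2 <- tr - det
  lw <- ifelse(l2 > 0, sqrt(l1 / l2), NA_real_)
  out <- data.frame(
    object_id = agg$id,
    area = agg$area,
    dry_mass = agg$dry_mass,
    mean_optical_thickness = agg$mean_ot,
    max_optical_thickness = agg$max_ot,
    volume = agg$volume,
    surface = agg$surface,
    sphericity = sph,
    length_width_ratio = lw,
    lw_undefined = !is.finite(lw),
    x = agg$cx, y = agg$cy,
    touches_border = agg$touches_border,
    unreliable = agg$n_px < 4L,
    time_h = image$time_h,
    well_id = image$well_id,
    stringsAsFactors = FALSE)
  class(out) <- c("cell_records", "data.frame")
  out
}

.empty_records <- function() {
  out <- data.frame(object_id = integer(), area = numeric(),
                    dry_mass = numeric(), mean_optical_thickness = numeric(),
                    max_optical_thickness = numeric(), volume = numeric(),
                    surface = numeric(), sphericity = numeric(),
                    length_width_ratio = numeric(), lw_undefined = logical(),
                    x = numeric(), y = numeric(), touches_border = logical(),
                    unreliable = logical(), time_h = numeric(),
                    well_id = character(), stringsAsFactors = FALSE)
  class(out) <- c("cell_records", "data.frame")
  out
}

#' Pair cell records with a co-registered fluorescence raster
#'
#' Adds a `fluorescence_mean` column: the mean over each object's
#' pixels of the fluorescence image after zeroing pixels below the
#' background threshold (background exclusion, default 50 arbitrary
#' units).
#'
#' @param records output of [measure()].
#' @param labels the [label_map()] the records were measured on.
#' @param fluor numeric matrix of fluorescence values, same
#'   dimensions as the label map.
#' @param background_threshold pixels strictly below this value are
#'   treated as background (set to 0) before averaging.
#' @return `records` with a `fluorescence_mean` column.
#' @export
pair_fluorescence <- function(records, labels, fluor,
                              background_threshold = 50) {
  stopifnot(inherits(labels, "label_map"), is.matrix(fluor))
  if (!all(dim(fluor) == dim(labels$labels)))
    stop(sprintf("fluorescence raster (%s) does not match label map (%s)",
                 paste(dim(fluor), collapse = "x"),
                 paste(dim(labels$labels), collapse = "x")))
  f <- fluor
  f[f < background_threshold] <- 0
  lab <- labels$labels
  sel <- which(lab > 0L)
  dt <- data.table::data.table(id = lab[sel], f = f[sel])
  agg <- dt[, list(fl = mean(f)), by = "id"]
  records$fluorescence_mean <- agg$fl[match(records$object_id, agg$id)]
  records
}

#' Summarise fluorescence by sphericity group
#'
#' Splits records at a sphericity boundary (default 0.25, below which
#' healthy spread endothelial cells sit) and summarises fluorescence
#' per group — the readout used to relate cell rounding to caspase
#' activity.
#'
#' @param records output of [pair_fluorescence()] (must carry
#'   `fluorescence_mean`).
#' @param boundary sphericity split point.
#' @return data frame with rows `below` (`sphericity < boundary`) and
#'   `above` (`>= boundary`): n, mean_fluorescence, sem, empty flag.
#' @export
split_by_sphericity <- function(records, boundary = 0.25) {
  if (is.null(records$fluorescence_mean))
    stop("records carry no fluorescence_mean; run pair_fluorescence() first")
  grp <- ifelse(records$sphericity < boundary, "below", "above")
  one <- function(g) {
    v <- records$fluorescence_mean[grp == g]
    data.frame(group = g, n = length(v),
               mean_fluorescence = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               empty = length(v) == 0)
  }
  rbind(one("below"), one("above"))
}
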