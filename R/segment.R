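#' Label map of segmented objects
#'
#' Integer raster with 0 = background and object ids contiguous from
#' 1, plus the pixel size needed to convert pixel counts to areas.
#'
#' @param labels integer matrix of labels.
#' @param pixel_size um per pixel.
#' @return object of class `label_map`.
#' @export
label_map <- function(labels, pixel_size) {
  stopifnot(is.matrix(labels), pixel_size > 0)
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be nonnegative")
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d x %d px, %d objects\n",
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  invisible(x)
}

#' Number of objects in a label map
#' @param x a [label_map()].
#' @return integer count.
#' @export
n_objects <- function(x) {
  stopifnot(inherits(x, "label_map"))
  max(x$labels)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge
# label pairs that touch diagonally with a union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, 0L)
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# Renumber labels to be contiguous from 1 (dropping empty ids).
.relabel <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0) return(lab)
  out <- lab
  out[lab > 0L] <- match(lab[lab > 0L], ids)
  out
}

#' Segment a phase image into labelled objects
#'
#' A documented, reproducible segmentation pipeline for OPD rasters:
#'
#' 1. Gaussian smoothing of the OPD topography (`smoothing_scale`).
#' 2. Otsu threshold on the smoothed image marks confident "core"
#'    object pixels.
#' 3. A permissive support mask (`opd > support_floor` on the raw
#'    image) recovers the full faint footprint of each object;
#'    support components that contain no core pixel are dropped.
#'    This hysteresis step keeps thin cell margins that a single
#'    global threshold would clip, which matters when integrated
#'    dry mass must be conserved.
#' 4. Optionally, touching cells are separated by an h-maxima
#'    marker-based watershed on the smoothed OPD topography
#'    (`watershed_tolerance` is the minimum OPD prominence of a
#'    seed; `min_seed_separation` sets the local-maximum search
#'    radius).
#'
#' Objects are 8-connected; an all-zero image yields an empty label
#' map rather than an error.
#'
#' @param image a [phase_image()].
#' @param min_seed_separation minimum distance between watershed
#'   seeds, um.
#' @param smoothing_scale Gaussian sigma, um (0 = no smoothing).
#' @param support_floor OPD floor (um) of the faint-footprint support
#'   mask. For noisy images raise this to ~3x the background noise SD.
#' @param watershed_tolerance h-maxima prominence, um OPD.
#' @param split_touching run the watershed split (disable for fields
#'   known to contain only isolated objects; the threshold stage is
#'   then the whole segmentation).
#' @return a [label_map()].
#' @export
segment <- function(image, min_seed_separation = 10, smoothing_scale = 2,
                    support_floor = 1e-4, watershed_tolerance = 0.05,
                    split_touching = TRUE) {
  stopifnot(inherits(image, "phase_image"))
  px <- image$optics$pixel_size
  m <- image$opd
  if (!all(is.finite(m))) stop("image must be finite-valued")
  if (max(m) <= 0)
    return(label_map(matrix(0L, nrow(m), ncol(m)), px))
  sm <- if (smoothing_scale > 0)
    EBImage::gblur(m, sigma = smoothing_scale / px) else m
  mx <- max(sm)
  th <- EBImage::otsu(EBImage::Image(sm / mx), range = c(0, 1)) * mx
  core <- sm > th
  if (!any(core))
    return(label_map(matrix(0L, nrow(m), ncol(m)), px))
  support <- (m > support_floor) | core
  lab <- .label8(support)
  keep <- sort(unique(lab[core & lab > 0L]))
  lab[!(lab %in% keep)] <- 0L
  lab <- .relabel(lab)
  if (split_touching && max(lab) > 0) {
    topo <- sm
    topo[lab == 0L] <- 0
    ext <- max(1L, round(min_seed_separation / px / 2))
    ws <- EBImage::watershed(EBImage::Image(topo), tolerance = watershed_tolerance,
                             ext = ext)
    ws <- matrix(as.integer(ws), nrow(m), ncol(m))
    # watershed can miss support-only pixels at the very rim; give
    # them the label of the object whose component they belong to
    orphan <- lab > 0L & ws == 0L
    if (any(orphan)) {
      ws2 <- EBImage::propagate(EBImage::Image(topo), EBImage::Image(ws),
                                mask = lab > 0L)
      ws <- matrix(as.integer(ws2), nrow(m), ncol(m))
    }
    # the watershed may only ever split a support component, never
    # fuse two: its neighbourhood search (ext) can bridge narrow
    # background gaps, so intersect its labels with the components
    sel <- lab > 0L & ws > 0L
    key <- (as.numeric(lab[sel]) - 1) * (max(ws) + 1) + ws[sel]
    out <- matrix(0L, nrow(m), ncol(m))
    out[sel] <- match(key, sort(unique(key)))
    lab <- out
  }
  label_map(lab, px)
}

#' Apply the debris size gate to a label map
#'
#' Partitions segmented objects into cells and debris by footprint
#' area. The default follows the convention of restricting
#' quantification to regions over 400 um^2: with `strict = TRUE`
#' an object is kept as a cell iff its area is strictly greater than
#' `min_area`; `strict = FALSE` uses `>=`.
#'
#' @param labels a [label_map()].
#' @param min_area gate threshold, um^2 (> 0).
#' @param strict strict inequality (default) or not.
#' @return list with `cells` (a [label_map()], ids renumbered),
#'   `debris` (a [label_map()]), and `summary`, a one-row data frame
#'   (n_total, n_cells, n_debris, debris_percent). The debris
#'   percentage of an empty map is 0 by convention.
#' @export
apply_size_gate <- function(labels, min_area = 400, strict = TRUE) {
  stopifnot(inherits(labels, "label_map"), min_area > 0)
  lab <- labels$labels
  px2 <- labels$pixel_size^2
  n <- max(lab)
  if (n == 0) {
    empty <- label_map(matrix(0L, nrow(lab), ncol(lab)), labels$pixel_size)
    return(list(cells = empty, debris = empty,
                summary = data.frame(n_total = 0L, n_cells = 0L,
                                     n_debris = 0L, debris_percent = 0)))
  }
  areas <- tabulate(lab[lab > 0L], nbins = n) * px2
  is_cell <- if (strict) areas > min_area else areas >= min_area
  cell_lab <- lab; cell_lab[!(lab %in% which(is_cell))] <- 0L
  deb_lab <- lab; deb_lab[!(lab %in% which(!is_cell))] <- 0L
  summary <- data.frame(n_total = n, n_cells = sum(is_cell),
                        n_debris = sum(!is_cell),
                        debris_percent = 100 * sum(!is_cell) / n)
  list(cells = label_map(.relabel(cell_lab), labels$pixel_size),
       debris = label_map(.relabel(deb_lab), labels$pixel_size),
       summary = summary)
}
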