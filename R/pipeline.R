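#' Assay run configuration
#'
#' Collects every tunable threshold of the pipeline in one object,
#' with the study-protocol values as defaults: the 400 um^2 debris
#' gate, the 50 AU fluorescence background threshold, the 0.25
#' sphericity boundary, morphology time bins of 0/12/24/36 h and an
#' hourly tubulogenesis course normalised to 1 h. A YAML file with any
#' subset of the fields can override the defaults, and named arguments
#' override both.
#'
#' @param path optional YAML file of overrides.
#' @param ... named overrides (e.g. `gate_min_area = 500`, or
#'   `optics = list(pixel_size = 1)`).
#' @return list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    optics = list(),               # passed to optics_config()
    gate_min_area = 400,           # um^2, strict
    gate_strict = TRUE,
    fluorescence_background = 50,  # AU
    sphericity_boundary = 0.25,
    min_seed_separation = 10,      # um
    smoothing_scale = 2,           # um
    support_floor = 1e-4,          # um OPD
    watershed_tolerance = 0.05,    # um OPD
    split_touching = TRUE,
    prune_length = 15,             # um
    junction_merge_radius = 5,     # um
    boundary_margin_px = 2,
    morphology_time_bins = c(0, 12, 24, 36),
    tube_baseline_h = 1,
    cell_cutoff_h = 4,
    seed = 1L)
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$optics <- do.call(optics_config, as.list(cfg$optics))
  with(cfg, stopifnot(gate_min_area > 0, fluorescence_background > 0,
                      sphericity_boundary > 0, prune_length > 0,
                      junction_merge_radius > 0, boundary_margin_px > 0,
                      all(diff(morphology_time_bins) > 0)))
  class(cfg) <- "run_config"
  cfg
}

.as_phase_image <- function(x, optics) {
  if (inherits(x, "phase_image")) return(x)
  if (is.character(x)) {
    img <- tryCatch(read_phase_tiff(x, optics = optics),
                    error = function(e)
                      stop(sprintf("unreadable frame '%s': %s", x, conditionMessage(e))))
    return(img)
  }
  stop("inputs must be phase_image objects or TIFF paths")
}

.segment_cfg <- function(image, cfg) {
  segment(image,
          min_seed_separation = cfg$min_seed_separation,
          smoothing_scale = cfg$smoothing_scale,
          support_floor = cfg$support_floor,
          watershed_tolerance = cfg$watershed_tolerance,
          split_touching = cfg$split_touching)
}

#' Run the monolayer morphology assay
#'
#' For each input frame: segment, apply the debris size gate, measure
#' the gated cells, and summarise per (well, time): cell count (also
#' as % of the count at the first time bin), mean area, mean
#' sphericity, mean length/width ratio and debris percentage.
#'
#' @param config a [run_config()].
#' @param inputs list of [phase_image()] objects (or TIFF paths), each
#'   carrying its `time_h` and `well_id`.
#' @param out_dir optional directory; when given, per-cell and summary
#'   CSVs, a gate-summary JSON and a run manifest are written there.
#' @return list: `cells` (per-cell records), `summary` (per frame),
#'   `gate` (per frame), `manifest`.
#' @export
run_morphology_assay <- function(config, inputs, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[3]
  frames <- lapply(inputs, .as_phase_image, optics = config$optics)
  cells <- list(); gates <- list(); summaries <- list()
  for (f in seq_along(frames)) {
    img <- frames[[f]]
    lab <- .segment_cfg(img, config)
    gate <- apply_size_gate(lab, min_area = config$gate_min_area,
                            strict = config$gate_strict)
    rec <- measure(img, gate$cells)
    g <- gate$summary
    g$time_h <- img$time_h; g$well_id <- img$well_id
    gates[[f]] <- g
    cells[[f]] <- rec
    summaries[[f]] <- data.frame(
      well_id = img$well_id, time_h = img$time_h,
      n_cells = nrow(rec),
      mean_area = if (nrow(rec)) mean(rec$area) else NA_real_,
      mean_sphericity = if (nrow(rec)) mean(rec$sphericity) else NA_real_,
      mean_lw = if (nrow(rec)) mean(rec$length_width_ratio, na.rm = TRUE) else NA_real_,
      mean_dry_mass = if (nrow(rec)) mean(rec$dry_mass) else NA_real_,
      debris_percent = g$debris_percent,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summaries)
  base_t <- config$morphology_time_bins[1]
  summary$count_pct_baseline <- NA_real_
  for (w in unique(summary$well_id)) {
    rows <- summary$well_id %in% w   # %in% is NA-safe
    i <- which(rows & summary$time_h == base_t)
    if (length(i) == 1 && summary$n_cells[i] > 0) {
      summary$count_pct_baseline[rows] <-
        100 * summary$n_cells[rows] / summary$n_cells[i]
    }
  }
  out <- list(cells = do.call(rbind, cells), summary = summary,
              gate = do.call(rbind, gates))
  out$manifest <- .write_outputs(config, out_dir, list(
    cells = out$cells, summary = out$summary, gate = out$gate),
    elapsed = proc.time()[3] - t0)
  out
}

#' Run the tubulogenesis assay
#'
#' For each hourly frame: build the tube mask, skeletonise to a
#' network graph, flag boundary-touching branches, and compute
#' network metrics; the series is then normalised to the baseline
#' frame (default 1 h). Frames up to `cell_cutoff_h` are additionally
#' segmented at cell level (beyond that, cells have coalesced into
#' tubes and single-cell segmentation is no longer meaningful).
#'
#' @param config a [run_config()].
#' @param inputs list of [phase_image()] (or TIFF paths) covering the
#'   baseline hour.
#' @param out_dir optional output directory (CSV + manifest).
#' @return list: `metrics` (per frame, raw + `pct_` columns),
#'   `cells` (early-frame per-cell records, possibly empty),
#'   `graphs` (list of `network_graph`), `manifest`.
#' @export
run_tubulogenesis_assay <- function(config, inputs, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[3]
  frames <- lapply(inputs, .as_phase_image, optics = config$optics)
  times <- vapply(frames, function(f) f$time_h, 0)
  if (!any(times == config$tube_baseline_h))
    stop(sprintf("series lacks the %g h baseline frame", config$tube_baseline_h))
  rows <- list(); graphs <- list(); cells <- list()
  for (f in seq_along(frames)) {
    img <- frames[[f]]
    mask <- make_tube_mask(img, smoothing_scale = config$smoothing_scale,
                           min_object_area = config$gate_min_area)
    g <- skeletonize_and_graph(mask, pixel_size = img$optics$pixel_size,
                               prune_length = config$prune_length,
                               junction_merge_radius = config$junction_merge_radius)
    g <- flag_boundary_branches(g, image_extent(img),
                                margin = config$boundary_margin_px *
                                  img$optics$pixel_size)
    graphs[[f]] <- g
    rows[[f]] <- network_metrics(g, time_h = img$time_h)
    if (!is.na(img$time_h) && img$time_h <= config$cell_cutoff_h) {
      lab <- .segment_cfg(img, config)
      gate <- apply_size_gate(lab, min_area = config$gate_min_area,
                              strict = config$gate_strict)
      cells[[length(cells) + 1L]] <- measure(img, gate$cells)
    }
  }
  metrics <- normalize_timecourse(do.call(rbind, rows),
                                  baseline_time_h = config$tube_baseline_h)
  out <- list(metrics = metrics,
              cells = if (length(cells)) do.call(rbind, cells) else .empty_records(),
              graphs = graphs)
  out$manifest <- .write_outputs(config, out_dir,
                                 list(network_metrics = metrics,
                                      early_cells = out$cells),
                                 elapsed = proc.time()[3] - t0)
  out
}

#' Run the concentration-response assay
#'
#' Segments and measures every well image, joins mean per-well shape
#' metrics with the plate map, fits the three-parameter logistic per
#' condition and experiment, and summarises potency/efficacy per
#' condition. Conditions with fewer than 3 distinct concentrations
#' are skipped with a warning.
#'
#' @param config a [run_config()].
#' @param inputs named list of [phase_image()] (or TIFF paths); names
#'   are well ids matching the plate map (alternatively the images'
#'   own `well_id` fields are used).
#' @param plate_map data frame with columns `well`, `condition`,
#'   `log10_conc_M`, `experiment`.
#' @param response `"length_width_ratio"` (default) or `"sphericity"`.
#' @param out_dir optional output directory.
#' @return list: `well_metrics`, `fits` (per condition x experiment),
#'   `potency` (condition summary), `manifest`.
#' @export
run_dose_response_assay <- function(config, inputs, plate_map,
                                    response = "length_width_ratio",
                                    out_dir = NULL) {
  stopifnot(inherits(config, "run_config"),
            all(c("well", "condition", "log10_conc_M", "experiment") %in%
                  names(plate_map)))
  t0 <- proc.time()[3]
  frames <- lapply(inputs, .as_phase_image, optics = config$optics)
  wells <- names(inputs)
  if (is.null(wells))
    wells <- vapply(frames, function(f) f$well_id, "")
  if (!all(plate_map$well %in% wells))
    stop("plate map refers to wells missing from the inputs")
  wm <- list()
  for (f in seq_along(frames)) {
    img <- frames[[f]]
    lab <- .segment_cfg(img, config)
    gate <- apply_size_gate(lab, min_area = config$gate_min_area,
                            strict = config$gate_strict)
    rec <- measure(img, gate$cells)
    wm[[f]] <- data.frame(well = wells[f],
                          mean_response = mean(rec[[response]], na.rm = TRUE),
                          n_cells = nrow(rec), stringsAsFactors = FALSE)
  }
  wm <- do.call(rbind, wm)
  # deterministic under well shuffling: order by plate map
  tab <- merge(plate_map, wm, by = "well", sort = TRUE)
  fits <- list(); conds <- character(); exps <- character()
  for (cond in sort(unique(tab$condition))) {
    sub_c <- tab[tab$condition == cond, , drop = FALSE]
    if (length(unique(sub_c$log10_conc_M)) < 3) {
      warning(sprintf("condition '%s' has fewer than 3 concentrations; skipped", cond))
      next
    }
    for (ex in sort(unique(sub_c$experiment))) {
      sub <- sub_c[sub_c$experiment == ex, , drop = FALSE]
      ft <- fit_3pl(data.frame(x = sub$log10_conc_M, y = sub$mean_response))
      fits[[length(fits) + 1L]] <- ft
      conds <- c(conds, cond); exps <- c(exps, as.character(ex))
    }
  }
  fitdf <- data.frame(condition = conds, experiment = exps,
                      top = vapply(fits, `[[`, 0, "top"),
                      bottom = vapply(fits, `[[`, 0, "bottom"),
                      pec50 = vapply(fits, `[[`, 0, "pec50"),
                      span = vapply(fits, `[[`, 0, "span"),
                      converged = vapply(fits, `[[`, TRUE, "converged"),
                      stringsAsFactors = FALSE)
  potency <- if (nrow(fitdf)) derive_potency_table(fitdf[fitdf$converged, ]) else NULL
  out <- list(well_metrics = wm, fits = fitdf, potency = potency)
  out$manifest <- .write_outputs(config, out_dir,
                                 list(well_metrics = wm, fits = fitdf,
                                      potency = potency),
                                 elapsed = proc.time()[3] - t0)
  out
}

# Write named tables as CSV plus a JSON manifest with config echo,
# package version, row counts, wall time and content hashes.
.write_outputs <- function(config, out_dir, tables, elapsed) {
  tables <- Filter(Negate(is.null), tables)
  manifest <- list(
    package = "qpihuvec",
    version = as.character(utils::packageVersion("qpihuvec")),
    config = .config_echo(config),
    row_counts = lapply(tables, nrow),
    elapsed_s = unname(elapsed),
    files = list())
  if (is.null(out_dir)) return(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE)
    manifest$files[[paste0(nm, ".csv")]] <- unname(tools::md5sum(path))
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

.config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$optics <- unclass(cfg$optics)
  cfg
}
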