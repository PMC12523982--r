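#' Fit a three-parameter logistic concentration-response curve
#'
#' Nonlinear least squares of the unit-Hill-slope logistic (see
#' [logistic3()]) to well-level responses. Initial values are taken
#' from the data (`Bottom0 = min(y)`, `Top0 = max(y)`, `LogEC500` = the
#' concentration nearest the half-range crossing); if the first fit
#' fails to converge, up to `restarts` refits are attempted with the
#' initial LogEC50 jittered by up to one log-unit. Parameter standard
#' errors come from the Jacobian at the optimum (the usual Gauss-Newton
#' covariance). The `converged` flag is honest: a fit that exhausts all
#' restarts is returned with `converged = FALSE` rather than an error.
#'
#' The curve orientation is chosen from the data by default
#' (`direction = "auto"`: sign of the covariance between `x` and `y`),
#' so descending responses such as caspase suppression fit with
#' `top` at the low-concentration plateau and span = top - bottom kept
#' nonnegative. Fitting a degenerate (flat) response returns
#' `converged = FALSE` or an infinite `se` on LogEC50.
#'
#' @param table data frame with columns `x` (log10 molar) and `y`
#'   (response); additional columns are ignored. At least 3 distinct
#'   `x` values are required.
#' @param direction `"auto"`, `"ascending"` or `"descending"`.
#' @param restarts maximum number of jittered refits.
#' @return object of class `logistic_fit`: list with `top`, `bottom`,
#'   `log_ec50`, `pec50` (= -log_ec50), `span` (= top - bottom), `se`
#'   (named vector for top/bottom/log_ec50), `converged`, `rss`,
#'   `direction` (+1/-1), `n`, and the fitted `model` (an `nls`
#'   object or `NULL`).
#' @examples
#' sim <- simulate_dose_response(1.87, 1.70, -10.34,
#'                               log_concentration_series(), 2, 0)
#' fit_3pl(sim$table)
#' @export
fit_3pl <- function(table, direction = c("auto", "ascending", "descending"),
                    restarts = 5L) {
  direction <- match.arg(direction)
  stopifnot(all(c("x", "y") %in% names(table)))
  x <- table$x; y <- table$y
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  if (length(unique(x)) < 3)
    stop("at least 3 distinct concentrations are required to fit a 3-parameter logistic")
  dirn <- switch(direction,
                 auto = if (stats::cov(x, y) >= 0) 1 else -1,
                 ascending = 1, descending = -1)
  b0 <- min(y); t0 <- max(y)
  half <- (b0 + t0) / 2
  l0 <- x[which.min(abs(y - half))]
  fit1 <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (10^(dirn * (log_ec50 - x)) + 1),
        start = start,
        data = data.frame(x = x, y = y),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  starts <- list(list(top = t0, bottom = b0, log_ec50 = l0))
  jit <- seq(-1, 1, length.out = restarts)
  for (j in jit)
    starts <- c(starts, list(list(top = t0, bottom = b0, log_ec50 = l0 + j)))
  model <- NULL
  for (s in starts) {
    m <- fit1(s)
    if (!is.null(m) && m$convInfo$isConv) { model <- m; break }
    if (!is.null(m) && is.null(model)) model <- m
  }
  if (is.null(model)) {
    return(structure(list(top = NA_real_, bottom = NA_real_,
                          log_ec50 = NA_real_, pec50 = NA_real_,
                          span = NA_real_,
                          se = c(top = NA_real_, bottom = NA_real_,
                                 log_ec50 = NA_real_),
                          converged = FALSE, rss = NA_real_,
                          direction = dirn, n = length(y), model = NULL),
                     class = "logistic_fit"))
  }
  cf <- stats::coef(model)
  se <- tryCatch(summary(model)$coefficients[, "Std. Error"],
                 error = function(e)
                   c(top = NA_real_, bottom = NA_real_, log_ec50 = NA_real_))
  se <- se[c("top", "bottom", "log_ec50")]
  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 log_ec50 = unname(cf["log_ec50"]),
                 pec50 = -unname(cf["log_ec50"]),
                 span = unname(cf["top"] - cf["bottom"]),
                 se = se, converged = isTRUE(model$convInfo$isConv),
                 rss = sum(stats::residuals(model)^2),
                 direction = dirn, n = length(y), model = model),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("three-parameter logistic fit\n")
  cat(sprintf("  top      %8.4g  (se %.3g)\n", x$top, x$se["top"]))
  cat(sprintf("  bottom   %8.4g  (se %.3g)\n", x$bottom, x$se["bottom"]))
  cat(sprintf("  logEC50  %8.4g  (se %.3g)   pEC50 %.4g\n",
              x$log_ec50, x$se["log_ec50"], x$pec50))
  cat(sprintf("  span     %8.4g   direction %+d   converged: %s   rss %.4g\n",
              x$span, x$direction, x$converged, x$rss))
  invisible(x)
}

#' Summarise per-experiment logistic fits into a potency table
#'
#' Aggregates experiment-level fits per condition into mean +/- SEM of
#' pEC50 and span, mirroring the conventional potency/efficacy table
#' layout (condition, pEC50, SEM, n, span, SEM). A condition with a
#' single experiment reports `NA` SEMs and is flagged.
#'
#' @param fits a list of `logistic_fit` objects, or a data frame with
#'   columns `condition`, `experiment`, `pec50`, `span`.
#' @param conditions character vector parallel to `fits` (ignored for
#'   the data-frame form).
#' @return data frame: condition, pec50, pec50_sem, n, span, span_sem,
#'   single_experiment flag. Only converged fits contribute.
#' @export
derive_potency_table <- function(fits, conditions = NULL) {
  if (is.data.frame(fits)) {
    df <- fits
    stopifnot(all(c("condition", "pec50", "span") %in% names(df)))
  } else {
    stopifnot(is.list(fits), !is.null(conditions),
              length(conditions) == length(fits))
    df <- data.frame(condition = conditions,
                     pec50 = vapply(fits, function(f) f$pec50, 0),
                     span = vapply(fits, function(f) f$span, 0),
                     converged = vapply(fits, function(f) f$converged, TRUE))
    df <- df[df$converged, , drop = FALSE]
  }
  sem <- function(v) if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(split(df, df$condition), function(d) {
    data.frame(condition = d$condition[1],
               pec50 = mean(d$pec50), pec50_sem = sem(d$pec50),
               n = nrow(d),
               span = mean(d$span), span_sem = sem(d$span),
               single_experiment = nrow(d) < 2,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Normalise responses to vehicle-treated wells (100%)
#'
#' @param values response values (any metric units).
#' @param vehicle_values responses of the vehicle wells; their mean
#'   defines 100%.
#' @return `100 * values / mean(vehicle_values)`.
#' @export
normalize_to_vehicle <- function(values, vehicle_values) {
  m <- mean(vehicle_values)
  if (!is.finite(m) || m <= 0)
    stop("vehicle mean must be positive to normalise")
  100 * values / m
}

#' Express a time series as a percentage of its baseline value
#'
#' @param values metric values per time point.
#' @param times corresponding times, hours.
#' @param baseline_time_h the baseline time (must be present in
#'   `times`).
#' @return data frame: time_h, value, percent_of_baseline. When the
#'   baseline value is 0 the percentage column is `NA` with a warning.
#' @export
percent_of_baseline <- function(values, times, baseline_time_h = 0) {
  stopifnot(length(values) == length(times))
  i <- which(times == baseline_time_h)
  if (length(i) != 1)
    stop("baseline time must appear exactly once in `times`")
  base <- values[i]
  pct <- if (is.finite(base) && base != 0) 100 * values / base else {
    warning("baseline value is zero; percentages undefined")
    rep(NA_real_, length(values))
  }
  data.frame(time_h = times, value = values, percent_of_baseline = pct)
}
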