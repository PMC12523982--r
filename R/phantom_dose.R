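#' Three-parameter logistic (unit Hill slope)
#'
#' The concentration-response model used throughout the package:
#' `Y = Bottom + (Top - Bottom) / (10^(LogEC50 - X) + 1)` for an
#' ascending response, where `X` is log10 molar concentration and
#' `Top`/`Bottom` are the curve plateaus. A descending response (e.g.
#' suppression of caspase activity with increasing growth factor) is
#' the same curve mirrored in `X`:
#' `Y = Bottom + (Top - Bottom) / (10^(X - LogEC50) + 1)`; in both
#' orientations `Top >= Bottom`, the half-maximal response sits at
#' `X = LogEC50`, and span = Top - Bottom.
#'
#' @param x log10 molar concentration (vector).
#' @param top,bottom plateaus, response units.
#' @param log_ec50 log10 molar EC50.
#' @param direction `1` for ascending (top reached at high
#'   concentration), `-1` for descending.
#' @return response values.
#' @export
logistic3 <- function(x, top, bottom, log_ec50, direction = 1) {
  stopifnot(direction %in% c(1, -1))
  bottom + (top - bottom) / (10^(direction * (log_ec50 - x)) + 1)
}

#' Simulate a concentration-response experiment
#'
#' Generates replicate well responses from the three-parameter
#' logistic with additive Gaussian well-to-well noise, together with a
#' truth record of the generating parameters.
#'
#' @param top,bottom,log_ec50 generating parameters (see [logistic3()]).
#' @param concentrations log10 molar concentrations (>= 1 value).
#' @param n_replicates wells per concentration (>= 1).
#' @param noise_sd Gaussian noise SD, response units (>= 0).
#' @param seed integer seed.
#' @param direction `1` ascending, `-1` descending.
#' @param experiment_id label stored in the table.
#' @return list with `table` (data frame: x, y, replicate_id,
#'   experiment_id) and `truth` (list of generating parameters).
#' @export
simulate_dose_response <- function(top, bottom, log_ec50, concentrations,
                                   n_replicates = 2L, noise_sd = 0,
                                   seed = 1L, direction = 1,
                                   experiment_id = "exp1") {
  if (length(concentrations) == 0) stop("empty concentration list")
  stopifnot(n_replicates >= 1, noise_sd >= 0, all(is.finite(concentrations)))
  x <- rep(concentrations, each = n_replicates)
  mu <- logistic3(x, top, bottom, log_ec50, direction)
  y <- .with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  tab <- data.frame(x = x, y = y,
                    replicate_id = rep(seq_len(n_replicates),
                                       times = length(concentrations)),
                    experiment_id = experiment_id,
                    stringsAsFactors = FALSE)
  truth <- list(top = top, bottom = bottom, log_ec50 = log_ec50,
                pec50 = -log_ec50, span = top - bottom,
                noise_sd = noise_sd, n_replicates = n_replicates,
                direction = direction, seed = seed)
  list(table = tab, truth = truth)
}

#' Log-spaced concentration series
#'
#' @param from,to molar concentrations bounding the series (e.g.
#'   `1e-13` for 100 fM to `3e-9` for 3 nM).
#' @param n number of concentrations.
#' @return log10 molar values, equally spaced.
#' @export
log_concentration_series <- function(from = 1e-13, to = 3e-9, n = 8L) {
  seq(log10(from), log10(to), length.out = n)
}
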