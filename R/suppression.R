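#' @name suppression
#' @title Success probabilities and success rates
#'
#' @description
#' A treated trap is declared a suppression success in a period when the
#' posterior probability that its relative density is at most the threshold
#' (default 0.20, i.e. at least 80% suppression) reaches 0.95. The
#' site-level success rate is the proportion of flagged traps.
NULL

#' Posterior success probability of one trap
#'
#' Monte-Carlo estimate of `P(theta <= threshold)`: `n_sim` samples are
#' drawn with replacement from the stored posterior draws and the fraction
#' at or below the threshold is returned. When at least `n_sim` draws are
#' stored the empirical CDF of the draws is used directly (the resampling
#' procedure is a Monte-Carlo approximation of exactly that CDF).
#'
#' @param theta_draws posterior draws of one trap's relative density.
#' @param threshold suppression threshold (comparison is `<=`).
#' @param n_sim number of posterior samples (default 10000).
#' @param seed RNG seed for the resampling step.
#' @return success probability in `[0, 1]`.
#' @export
success_probability <- function(theta_draws, threshold = 0.20, n_sim = 10000,
                                seed = NULL) {
  if (!length(theta_draws)) stop("empty draw set")
  if (length(theta_draws) >= n_sim) return(mean(theta_draws <= threshold))
  if (!is.null(seed)) set.seed(seed %% .Machine$integer.max)
  sim <- sample(theta_draws, n_sim, replace = TRUE)
  mean(sim <= threshold)
}

#' Assess suppression success across traps and periods
#'
#' @param fit a `sit_fit` from [fit_spatial_model()].
#' @param threshold relative-density success threshold (default the spec's
#'   0.20).
#' @param alpha posterior probability needed to flag success (default 0.95).
#' @param n_sim,seed passed to [success_probability()].
#' @return object of class `"success_assessment"`: `by_trap` data frame
#'   (`trap_id`, `period`, `theta_mean`, `p_success`, `success`) and
#'   `by_period` data frame (`period`, `success_rate`, `n_traps`).
#' @export
assess_success <- function(fit, threshold = 0.20, alpha = 0.95,
                           n_sim = 10000, seed = NULL) {
  td <- .theta_draws(fit)
  periods <- fit$spec$periods
  traps <- fit$spec$network$traps$trap_id
  J <- length(traps)
  if (!is.null(seed)) set.seed(seed %% .Machine$integer.max)
  rows <- do.call(rbind, lapply(seq_along(periods), function(i) {
    m <- td$trap[, , i, drop = TRUE]
    p <- vapply(seq_len(J), function(j)
      success_probability(m[, j], threshold, n_sim), numeric(1))
    data.frame(trap_id = traps, period = periods[i],
               theta_mean = colMeans(m), p_success = p,
               success = p >= alpha)
  }))
  rownames(rows) <- NULL
  by_period <- data.frame(
    period = periods,
    success_rate = vapply(periods, function(pp)
      mean(rows$success[rows$period == pp]), numeric(1)),
    n_traps = J)
  structure(list(by_trap = rows, by_period = by_period,
                 threshold = threshold, alpha = alpha),
            class = "success_assessment")
}

#' Site-level success rate for one period
#'
#' @param assessment a `success_assessment`.
#' @param period exposure period index.
#' @return proportion of flagged traps.
#' @export
success_rate <- function(assessment, period) {
  stopifnot(inherits(assessment, "success_assessment"))
  row <- assessment$by_period[assessment$by_period$period == period, ]
  if (!nrow(row)) stop("period ", period, " not present in the assessment")
  row$success_rate
}

#' @export
print.success_assessment <- function(x, ...) {
  cat(sprintf("suppression success at threshold %.2f (P >= %.2f):\n",
              x$threshold, x$alpha))
  print(x$by_period, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Export success maps as GeoJSON choropleths
#'
#' Writes, per period, one FeatureCollection whose cell features carry the
#' posterior mean relative density, the success probability and the success
#' flag.
#'
#' @param network `trap_network` (must match the assessment's trap order).
#' @param assessment a `success_assessment`.
#' @param dir output directory.
#' @param periods which periods to export (default all); an empty selection
#'   is an error.
#' @return paths of written files, invisibly.
#' @export
export_success_maps <- function(network, assessment, dir,
                                periods = unique(assessment$by_trap$period)) {
  stopifnot(inherits(network, "trap_network"))
  if (!length(periods)) stop("empty period selection")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (pp in periods) {
    sub <- assessment$by_trap[assessment$by_trap$period == pp, ]
    if (!nrow(sub)) stop("period ", pp, " not present in the assessment")
    if (!identical(as.character(sub$trap_id), network$traps$trap_id))
      stop("trap order mismatch between network and assessment")
    props <- data.frame(trap_id = sub$trap_id, theta_mean = sub$theta_mean,
                        p_success = sub$p_success, success = sub$success)
    path <- file.path(dir, sprintf("success_period_%s.geojson", pp))
    write_choropleth(network$cells, props, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
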