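#' @name standardization
#' @title Standardizing counts into relative densities
#'
#' @description
#' Trap counts are grouped into exposure periods of roughly one month. For
#' each period the expected density E is the mean per-trap-session count at
#' the control site; the observed relative density of a treated trap is its
#' count divided by E. Where treated and control sites differed before the
#' releases began, a baseline multiplier (the pre-release treated/control
#' density ratio, estimated by a negative-binomial model) rescales E.
NULL

#' Exposure period scheme
#'
#' Consecutive half-open intervals `[start, start + len)` defined by a start
#' date and a list of period lengths in days. The La Reunion trial used
#' five periods alternating 31 and 30 days from 2021-03-04; the Spanish
#' trials used four 34-day periods from 2021-06-01.
#'
#' @param start_date first day of the first period (Date or ISO string).
#' @param period_lengths positive integer day counts, one per period.
#' @return object of class `"period_scheme"`.
#' @export
period_scheme <- function(start_date, period_lengths) {
  start_date <- as.Date(start_date)
  stopifnot(!is.na(start_date), length(period_lengths) >= 1, all(period_lengths > 0))
  breaks <- start_date + c(0, cumsum(period_lengths))
  structure(list(start_date = start_date,
                 period_lengths = as.integer(period_lengths),
                 breaks = breaks),
            class = "period_scheme")
}

#' @rdname period_scheme
#' @export
la_reunion_scheme <- function() period_scheme("2021-03-04", c(31L, 30L, 31L, 30L, 31L))

#' @rdname period_scheme
#' @export
spain_scheme <- function() period_scheme("2021-06-01", rep(34L, 4))

#' Map dates to exposure periods
#'
#' @param date Date vector.
#' @param scheme a [period_scheme()].
#' @return integer period index per date; `NA` outside the scheme window.
#' @export
assign_period <- function(date, scheme) {
  stopifnot(inherits(scheme, "period_scheme"))
  date <- as.Date(date)
  idx <- findInterval(as.numeric(date), as.numeric(scheme$breaks),
                      rightmost.closed = FALSE)
  idx[idx < 1 | idx > length(scheme$period_lengths)] <- NA_integer_
  idx
}

#' Expected density from control-site sessions
#'
#' The arithmetic mean of per-session counts over all control trap-sessions
#' falling in a period, for one (species, stage) key.
#'
#' @param control_records `trap_records` from the control site.
#' @param period period index.
#' @param scheme a [period_scheme()].
#' @param species,stage keys selecting the series.
#' @return mean count per control trap-session (may be 0).
#' @export
expected_density <- function(control_records, period, scheme, species, stage) {
  r <- control_records
  sel <- r$zone == "control" & r$species == species & r$stage == stage &
    !is.na(assign_period(r$date, scheme)) & assign_period(r$date, scheme) == period
  if (!any(sel))
    stop(sprintf("no control sessions in period %d for %s/%s", period, species, stage))
  mean(r$count[sel])
}

#' Observed relative density
#'
#' @param y observed count.
#' @param E_effective effective expected density (baseline multiplier already
#'   applied); must be positive.
#' @return `y / E_effective`.
#' @export
relative_density_observed <- function(y, E_effective) {
  if (any(E_effective <= 0))
    stop("relative density undefined: effective expected density is zero")
  y / E_effective
}

#' Standardize a trial's counts into per-(trap, period) observations
#'
#' Aggregates treated-site sessions per (trap, period): y is the sum of the
#' trap's session counts in the period and the effective expectation is
#' `m * E_period * n_sessions`, so that theta = y / E stays a per-session
#' ratio even when traps miss sessions.
#'
#' @param records `trap_records` containing both treated and control zones.
#' @param scheme a [period_scheme()].
#' @param species,stage series to standardize.
#' @param baseline_multiplier pre-release treated/control density ratio `m`
#'   (default 1).
#' @return data frame of class `"standardized_obs"` with columns `trap_id`,
#'   `period`, `n_sessions`, `y`, `E_period`, `E` (effective), `theta_obs`
#'   (`NA` where E is zero, flagged in `theta_defined`).
#' @export
standardize_observations <- function(records, scheme, species, stage,
                                     baseline_multiplier = 1) {
  stopifnot(baseline_multiplier > 0)
  r <- as.data.frame(records)
  r$period <- assign_period(r$date, scheme)
  r <- r[!is.na(r$period) & r$species == species & r$stage == stage, ]
  if (!nrow(r)) stop("no sessions in the scheme window for ", species, "/", stage)
  if (!any(r$zone == "control")) stop("no control-zone sessions: cannot form expected density")
  if (!any(r$zone == "treated")) stop("no treated-zone sessions to standardize")
  ctrl <- r[r$zone == "control", ]
  E_per <- tapply(ctrl$count, ctrl$period, mean)
  trt <- r[r$zone == "treated", ]
  agg <- aggregate(count ~ trap_id + period, data = trt,
                   FUN = function(v) c(sum = sum(v), n = length(v)))
  out <- data.frame(trap_id = agg$trap_id, period = agg$period,
                    n_sessions = agg$count[, "n"], y = agg$count[, "sum"],
                    stringsAsFactors = FALSE)
  out$E_period <- as.numeric(E_per[as.character(out$period)])
  if (any(is.na(out$E_period)))
    stop("periods with treated sessions but no control sessions: ",
         paste(unique(out$period[is.na(out$E_period)]), collapse = ", "))
  out$E <- baseline_multiplier * out$E_period * out$n_sessions
  out$theta_defined <- out$E > 0
  out$theta_obs <- ifelse(out$theta_defined, out$y / out$E, NA_real_)
  out <- out[order(out$period, out$trap_id), ]
  rownames(out) <- NULL
  class(out) <- c("standardized_obs", "data.frame")
  out
}

#' Pre-release baseline ratio via a negative-binomial model
#'
#' Fits a negative-binomial regression (log link, variance mu + mu^2/k) of
#' treated-site counts with offset log(E) and an exposure-month factor whose
#' reference level 0 is the pre-release window. The exponentiated intercept
#' estimates the treated/control density ratio before releases; it is used
#' as a multiplier of the expected density where the sites differed at
#' baseline.
#'
#' @param y treated-site counts.
#' @param exposure factor (or coercible) with reference level `"0"` =
#'   pre-release.
#' @param E expected densities (control-standardized), positive.
#' @return object of class `"baseline_fit"`: `intercept`, `ratio`
#'   (= exp(intercept)), `ci95` (Wald), `dispersion` (NB size k), `model`.
#' @export
fit_negbin_baseline <- function(y, exposure, E) {
  exposure <- stats::relevel(factor(exposure), ref = "0")
  if (nlevels(exposure) < 2)
    stop("need at least two exposure levels including the pre-release reference '0'")
  if (all(y == 0)) stop("all counts are zero: baseline ratio is not estimable")
  if (any(E <= 0)) stop("expected densities must be positive")
  df <- data.frame(y = y, exposure = exposure, logE = log(E))
  fit <- tryCatch(
    MASS::glm.nb(y ~ exposure + offset(logE), data = df),
    error = function(e) stop("negative-binomial fit failed to converge: ",
                             conditionMessage(e)))
  b0 <- unname(coef(fit)[1])
  se <- sqrt(vcov(fit)[1, 1])
  ratio <- exp(b0)
  # delta-method Wald interval on the ratio scale (symmetric around the ratio)
  ci <- ratio + c(-1, 1) * qnorm(0.975) * ratio * se
  structure(list(intercept = b0, ratio = ratio, ci95 = ci,
                 dispersion = fit$theta, model = fit),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("pre-release treated/control density ratio: %.2f [%.2f, %.2f] (95%% CI), NB dispersion k = %.2f\n",
              x$ratio, x$ci95[1], x$ci95[2], x$dispersion))
  invisible(x)
}
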