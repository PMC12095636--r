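#' @name release-metrics
#' @title Release-campaign summary statistics
#'
#' @description
#' Campaign-level descriptors of the sterile-male release effort: weekly
#' release density (males/ha/week), the sterile-to-wild male capture ratio
#' with zero-safe period grouping, and marked-male recapture fractions by
#' zone.
NULL

#' Weekly sterile-male release density
#'
#' @param total total sterile males released over the campaign.
#' @param weeks campaign length in weeks (> 0).
#' @param area_ha treated area in hectares (> 0).
#' @param round_result report rounded to the nearest integer (default), as
#'   the densities are conventionally quoted.
#' @return males/ha/week.
#' @export
weekly_release_density <- function(total, weeks, area_ha, round_result = TRUE) {
  if (weeks <= 0 || area_ha <= 0) stop("weeks and area_ha must be positive")
  if (total < 0) stop("total released must be non-negative")
  d <- total / (weeks * area_ha)
  if (round_result) round(d) else d
}

#' Sterile-to-wild male capture ratio with zero-safe grouping
#'
#' Periods are merged greedily left to right until every group has at least
#' one wild male in the denominator; the ratio is reported per group and
#' overall as the pooled ratio `sum(s) / sum(w)` (equal to the
#' capture-weighted mean of the group ratios).
#'
#' @param marked sterile (marked) male captures per period.
#' @param wild wild male captures per period (aligned with `marked`).
#' @return list with `groups` (data frame: first/last period, s, w, ratio)
#'   and `overall` (pooled ratio).
#' @export
sterile_wild_ratio <- function(marked, wild) {
  stopifnot(length(marked) == length(wild), all(marked >= 0), all(wild >= 0))
  if (sum(wild) == 0) stop("ratio undefined: no wild males captured in any period")
  first <- integer(0); last <- integer(0); s <- numeric(0); w <- numeric(0)
  i <- 1L; n <- length(marked)
  while (i <= n) {
    j <- i
    while (sum(wild[i:j]) == 0 && j < n) j <- j + 1L
    first <- c(first, i); last <- c(last, j)
    s <- c(s, sum(marked[i:j])); w <- c(w, sum(wild[i:j]))
    i <- j + 1L
  }
  # a trailing group without wild captures merges backwards into its neighbor
  k <- length(w)
  if (w[k] == 0 && k > 1) {
    s[k - 1] <- s[k - 1] + s[k]; w[k - 1] <- w[k - 1] + w[k]
    last[k - 1] <- last[k]
    first <- first[-k]; last <- last[-k]; s <- s[-k]; w <- w[-k]
  }
  groups <- data.frame(first_period = first, last_period = last,
                       s = s, w = w, ratio = s / w)
  list(groups = groups, overall = sum(s) / sum(w))
}

#' Marked-male recapture fraction of one zone
#'
#' Fraction of all recaptured marked sterile males that were caught in a
#' focus zone; the denominator includes every zone where marked males were
#' recaptured (neighboring release zones and control sites alike).
#'
#' @param zone_counts named vector of marked-male captures by zone.
#' @param focus_zone zone name.
#' @return fraction in `[0, 1]`.
#' @export
recapture_fraction <- function(zone_counts, focus_zone) {
  total <- sum(zone_counts)
  if (total <= 0) stop("no recaptured marked males: fraction undefined")
  if (!focus_zone %in% names(zone_counts))
    stop("unknown zone: ", focus_zone)
  unname(zone_counts[focus_zone] / total)
}

#' Summarize a release-event log
#'
#' @param events a `release_events` data frame (one site).
#' @param area_ha treated area in hectares.
#' @return list: `total_released`, `weeks` (span between first and last
#'   release, inclusive, in whole weeks), `density` (males/ha/week),
#'   `n_events`.
#' @export
release_summary <- function(events, area_ha) {
  events <- release_events(as.data.frame(events))
  total <- sum(events$n_males)
  weeks <- max(1, ceiling(as.numeric(max(events$date) - min(events$date) + 1) / 7))
  list(total_released = total, weeks = weeks, area_ha = area_ha,
       density = weekly_release_density(total, weeks, area_ha),
       n_events = nrow(events))
}
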