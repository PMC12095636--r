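#' Published summary of the seven trial datasets
#'
#' Loads the packaged table describing the seven treated/control dataset
#' pairs of the 2021 boosted-SIT field trials (La Reunion; La Vilavella and
#' Polinya de Xuquer East in the Valencia region): site, species, life
#' stage, zone role, area (ha), sterile-male release intensity
#' (males/week/ha, treated zones only), number of traps, number of trapping
#' sessions (traps x collection dates) and total counts over the study.
#'
#' @return data frame with one row per (site, species, stage, zone).
#' @export
trial_datasets_table <- function() {
  path <- system.file("extdata", "table1_datasets.csv", package = "boostsit")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$site, df$species, df$stage, df$zone)
  stopifnot(!anyDuplicated(key))
  df
}

#' Sum a column of the trial summary table over selected rows
#'
#' Cross-totals of the trial table (e.g. all eggs collected in one region,
#' all sessions for a life stage) are how the trial reports its headline
#' sample sizes; this sums one integer field over a row selection.
#'
#' @param fixture data frame as returned by [trial_datasets_table()].
#' @param filter either a predicate `function(df) -> logical` or a named
#'   list of column = value constraints (value may be a vector).
#' @param field one of `"total_count"`, `"n_sessions"`, `"n_traps"`.
#' @return integer sum over the matching rows.
#' @export
table_totals <- function(fixture, filter, field = c("total_count", "n_sessions", "n_traps")) {
  field <- match.arg(field)
  keep <- if (is.function(filter)) {
    filter(fixture)
  } else if (is.list(filter)) {
    sel <- rep(TRUE, nrow(fixture))
    for (nm in names(filter)) sel <- sel & fixture[[nm]] %in% filter[[nm]]
    sel
  } else stop("filter must be a predicate function or a named list")
  keep <- which(keep)
  if (!length(keep)) stop("filter selects no rows of the trial table")
  as.integer(sum(fixture[[field]][keep]))
}

#' Release-campaign constants of the three 2021 trials
#'
#' The raw campaign numbers reported for each trial: total sterile males
#' released, campaign length in weeks, treated area, and the marked-male
#' recapture counts by zone for the Polinya de Xuquer site (whose eastern
#' boosted-SIT males were also recaptured in the contiguous western
#' non-boosted zone and at the Albalat control site).
#'
#' @return nested list of campaign constants keyed by site.
#' @export
campaign_constants <- function() {
  list(
    la_reunion = list(total_released = 59972L, weeks = 17L, area_ha = 10),
    la_vilavella = list(total_released = 3892075L, weeks = 41L, area_ha = 35),
    polinya_east = list(total_released = 2470465L, weeks = 41L, area_ha = 23),
    polinya_recaptures = c(west = 450L, east = 2225L, control = 14L)
  )
}

#' Observed mean relative egg densities by treatment year (La Vilavella)
#'
#' Annual mean observed relative densities of Aedes albopictus eggs in
#' La Vilavella under non-boosted SIT (2020, 2022) and boosted SIT (2021),
#' with the reported one-sided permutation p-values for the pairwise
#' differences (9999 block permutations).
#'
#' @return list with `annual_means` (named numeric) and `comparisons`
#'   (data frame of pairwise differences and p-values).
#' @export
regime_comparison_table <- function() {
  list(
    annual_means = c(`2020` = 0.63, `2021` = 0.49, `2022` = 0.75),
    comparisons = data.frame(
      first = c("2020", "2022", "2022"),
      second = c("2021", "2021", "2020"),
      delta_o = c(0.14, 0.26, 0.13),
      p_value = c(0.0081, 0.0001, 0.0419)
    )
  )
}
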