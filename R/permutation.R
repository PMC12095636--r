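#' @name comparison
#' @title Block permutation test between treatment years
#'
#' @description
#' Annual mean relative densities from a balanced (year x trap x month)
#' design are compared by permuting the year labels independently within
#' every (trap, month) block, which preserves the design while breaking any
#' association with year. The one-sided p-value uses the add-one rule
#' `(1 + #{delta_perm >= delta_o}) / (n_perm + 1)`, whose smallest
#' attainable value with 9999 permutations is 0.0001.
NULL

#' Balanced relative-density dataset for permutation testing
#'
#' @param df data frame with columns `year`, `trap_id`, `month`,
#'   `theta_obs`; every (year, trap, month) cell must be present exactly
#'   once and at least two years are required.
#' @return validated data frame of class `"permutation_dataset"`.
#' @export
permutation_dataset <- function(df) {
  stopifnot(all(c("year", "trap_id", "month", "theta_obs") %in% names(df)))
  df <- as.data.frame(df)
  years <- sort(unique(df$year))
  if (length(years) < 2) stop("at least two years are required")
  tab <- table(df$year, df$trap_id, df$month)
  if (any(tab != 1))
    stop("unbalanced design: every (year, trap, month) cell must appear exactly once")
  class(df) <- c("permutation_dataset", "data.frame")
  df
}

#' Annual mean relative density
#'
#' @param dataset a [permutation_dataset()].
#' @param year year label.
#' @return mean of `theta_obs` over all (trap, month) cells of that year.
#' @export
annual_mean_theta <- function(dataset, year) {
  sel <- dataset$year == year
  if (!any(sel)) stop("year ", year, " not present")
  mean(dataset$theta_obs[sel])
}

#' Trap-by-month block permutation test
#'
#' Tests whether the annual mean relative density of `year_a` exceeds that
#' of `year_b` beyond what label exchange within (trap, month) blocks can
#' produce. The observed statistic is `delta_o = mean(year_a) -
#' mean(year_b)`; each permutation independently and uniformly shuffles the
#' two year labels within every block and recomputes the difference of the
#' annual grand means.
#'
#' @param dataset a [permutation_dataset()].
#' @param year_a,year_b years to compare (one-sided: a minus b).
#' @param n_perm number of random permutations (default 9999).
#' @param seed RNG seed.
#' @return object of class `"permutation_result"`: `delta_o`, `p_value`,
#'   `null_draws`, `n_perm`, `seed`, `years`.
#' @export
block_permutation_test <- function(dataset, year_a, year_b, n_perm = 9999,
                                   seed = 1) {
  dataset <- permutation_dataset(as.data.frame(dataset))
  if (n_perm < 1) stop("n_perm must be at least 1")
  sub <- dataset[dataset$year %in% c(year_a, year_b), ]
  if (!all(c(year_a, year_b) %in% sub$year)) stop("both years must be present")
  blk <- function(x) paste(x$trap_id, x$month, sep = "\r")
  da <- sub[sub$year == year_a, ]; da <- da[order(blk(da)), ]
  db <- sub[sub$year == year_b, ]; db <- db[order(blk(db)), ]
  stopifnot(identical(blk(da), blk(db)))
  d <- da$theta_obs - db$theta_obs  # per-block difference, aligned by (trap, month)
  B <- length(d)
  delta_o <- mean(d)
  set.seed(seed %% .Machine$integer.max)
  # within each block a uniform shuffle of two labels either keeps or swaps
  # the pair, each with probability 1/2; delta_perm = mean(sign * d)
  signs <- matrix(ifelse(runif(n_perm * B) < 0.5, 1, -1), n_perm, B)
  null_draws <- as.numeric(signs %*% d) / B
  p <- (1 + sum(null_draws >= delta_o - 1e-12)) / (n_perm + 1)
  structure(list(delta_o = delta_o, null_draws = null_draws, p_value = p,
                 n_perm = n_perm, seed = seed, years = c(year_a, year_b)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("block permutation test %s vs %s: delta_o = %.4f, P(>= delta_o) = %.4f (%d permutations)\n",
              x$years[1], x$years[2], x$delta_o, x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname block_permutation_test
#' @param x a `permutation_result`.
#' @param path output path for a JSON summary.
#' @export
write_permutation_result <- function(x, path) {
  jsonlite::write_json(list(delta_o = x$delta_o, p_value = x$p_value,
                            n_perm = x$n_perm, seed = x$seed,
                            years = as.character(x$years)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
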