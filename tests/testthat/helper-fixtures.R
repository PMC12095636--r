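# shared fixtures built in code

unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

square_m <- function(side) rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))

# small two-trap network inside a 100 m square (cells: left/right halves)
two_trap_network <- function() {
  build_trap_network(rbind(c(25, 50), c(75, 50)), square_m(100))
}

# synthetic trap records: n sessions per trap over given dates
make_records <- function(trap_ids, site_id, zone, dates, counts,
                         species = "albopictus", stage = "egg") {
  grid <- expand.grid(trap_id = trap_ids, date = dates,
                      stringsAsFactors = FALSE)
  trap_records(data.frame(
    trap_id = grid$trap_id, site_id = site_id, zone = zone,
    species = species, stage = stage, date = grid$date,
    count = counts, stringsAsFactors = FALSE))
}

# a hand-crafted fit object with known draws, for identities on
# fitted_theta / goodness_of_fit (bypasses MCMC)
fake_fit <- function(b_draws, u_draws, periods, trap_ids,
                     y = NULL, offset = NULL, X = NULL, trap_index = NULL,
                     obs = NULL) {
  spec <- list(periods = periods,
               network = list(traps = data.frame(trap_id = trap_ids)),
               y = y, offset = offset, X = X, trap_index = trap_index,
               obs = obs)
  structure(list(draws = list(b = b_draws, u = u_draws,
                              sigma = rep(0, nrow(b_draws)),
                              phi = rep(0, nrow(b_draws)),
                              chain = rep(1, nrow(b_draws))),
                 spec = spec),
            class = "sit_fit")
}

# balanced year x trap x month dataset from a matrix of theta values
# (rows = blocks in trap-month order, cols = years)
perm_data <- function(theta_by_year, traps = NULL, months = NULL) {
  Y <- ncol(theta_by_year)
  years <- 2019 + seq_len(Y)
  if (is.null(traps)) traps <- paste0("t", seq_len(nrow(theta_by_year)))
  if (is.null(months)) months <- 1
  grid <- expand.grid(trap_id = traps, month = months, stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(Y), function(k)
    data.frame(year = years[k], trap_id = grid$trap_id, month = grid$month,
               theta_obs = theta_by_year[, k])))
}
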