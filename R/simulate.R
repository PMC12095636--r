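#' @name synthetic-data
#' @title Synthetic suppression trials with known ground truth
#'
#' @description
#' Generates complete synthetic trials mirroring the generative structure
#' of the suppression model: a control site whose per-session counts follow
#' the seasonal intensity profile, and a treated site whose counts are
#' thinned by a known per-period suppression profile and modulated by a
#' BYM2 spatial field over the trap network. Optional negative-binomial
#' overdispersion and an additive immigration floor emulate features of
#' real surveillance data. All truth (field, profile, seeds) is returned so
#' recovery can be scored.
NULL

#' Configuration of a synthetic trial
#'
#' Defaults emulate the Mediterranean trial design: four 34-day exposure
#' periods, 1 trap/ha layouts, weekly sessions aggregated to 4 per trap per
#' period, a moderate control intensity, and a suppression profile that
#' deepens over the campaign.
#'
#' @param J_treated,J_control trap counts (layout density is 1 trap/ha, so
#'   these set the site areas in ha).
#' @param scheme a [period_scheme()] (default [spain_scheme()]).
#' @param lambda control intensity per period: expected counts per
#'   trap-session (recycled to the number of periods).
#' @param theta_true true suppression profile per period.
#' @param sigma_u,phi BYM2 field parameters for the treated site.
#' @param dispersion negative-binomial size parameter `k` (variance
#'   `mu + mu^2/k`); `Inf` (default) gives Poisson counts.
#' @param sessions_per_period trapping sessions per trap per period.
#' @param theta_floor additive immigration floor on the treated mean
#'   (emulates re-invasion by gravid females; default 0).
#' @param species,stage labels for the generated records.
#' @param seed trial seed; all component seeds derive from it.
#' @return object of class `"trial_config"`.
#' @export
trial_config <- function(J_treated = 30, J_control = 20,
                         scheme = spain_scheme(),
                         lambda = 20,
                         theta_true = c(1.0, 0.5, 0.25, 0.10),
                         sigma_u = 0.5, phi = 0.5,
                         dispersion = Inf,
                         sessions_per_period = 4,
                         theta_floor = 0,
                         species = "albopictus", stage = "egg",
                         seed = 1) {
  I <- length(scheme$period_lengths)
  lambda <- rep_len(lambda, I)
  if (length(theta_true) != I)
    stop("theta_true must have one value per period (", I, ")")
  stopifnot(all(lambda >= 0), all(theta_true >= 0), sigma_u >= 0,
            phi >= 0, phi <= 1, dispersion > 0, sessions_per_period >= 1,
            theta_floor >= 0, J_treated >= 1, J_control >= 1)
  structure(list(J_treated = J_treated, J_control = J_control, scheme = scheme,
                 lambda = lambda, theta_true = theta_true, sigma_u = sigma_u,
                 phi = phi, dispersion = dispersion,
                 sessions_per_period = as.integer(sessions_per_period),
                 theta_floor = theta_floor, species = species, stage = stage,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Random trap layout at 1 trap/ha
#'
#' Rejection-samples J points inside a boundary polygon with a minimum
#' pairwise separation of half the nominal inter-trap spacing
#' `sqrt(area / J)`.
#'
#' @param J number of traps.
#' @param boundary polygon (open-ring matrix); default a square of J ha.
#' @param seed RNG seed.
#' @param min_sep minimum pairwise separation in meters; defaults to half
#'   the nominal inter-trap spacing `sqrt(area / J)`.
#' @return J x 2 coordinate matrix (meters).
#' @export
generate_layout <- function(J, boundary = NULL, seed = 1, min_sep = NULL) {
  stopifnot(J >= 1)
  if (is.null(boundary)) {
    side <- sqrt(J * 1e4)        # 1 trap/ha
    boundary <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  }
  set.seed(seed %% .Machine$integer.max)
  area <- polygon_area(boundary)
  if (is.null(min_sep)) min_sep <- 0.5 * sqrt(area / J)
  bb <- apply(boundary, 2, range)
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pts) < J) {
    tries <- tries + 1L
    if (tries > 10000L * J)
      stop("boundary too small for ", J, " traps at separation ", round(min_sep, 1), " m")
    cand <- c(runif(1, bb[1, 1], bb[2, 1]), runif(1, bb[1, 2], bb[2, 2]))
    if (!point_in_polygon(matrix(cand, 1), boundary)) next
    if (nrow(pts) && min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2, byrow = TRUE))^2))) < min_sep) next
    pts <- rbind(pts, cand)
  }
  attr(pts, "boundary") <- boundary
  pts
}

#' Simulate a BYM2 spatial field on a trap network
#'
#' `u = sigma_u (sqrt(phi) w* + sqrt(1 - phi) v)` with `w*` the scaled
#' intrinsic CAR field drawn in the eigenbasis of the precision conditioned
#' on the (per-component) sum-to-zero constraint, and `v` iid standard
#' normal.
#'
#' @param network a `trap_network`.
#' @param sigma_u field standard deviation (>= 0).
#' @param phi mixing proportion in `[0, 1]`.
#' @param seed RNG seed.
#' @return numeric field of length J with attributes `w_star` and `v`.
#' @export
simulate_bym2_field <- function(network, sigma_u, phi, seed = 1) {
  stopifnot(inherits(network, "trap_network"))
  if (sigma_u < 0) stop("sigma_u must be non-negative")
  stopifnot(phi >= 0, phi <= 1)
  set.seed(seed %% .Machine$integer.max)
  basis <- network$basis
  J <- nrow(network$traps)
  z <- rnorm(length(basis$zprec), 0, 1 / sqrt(basis$zprec))
  wstar <- as.numeric(basis$U %*% z)
  v <- rnorm(J)
  u <- sigma_u * (sqrt(phi) * wstar + sqrt(1 - phi) * v)
  attr(u, "w_star") <- wstar
  attr(u, "v") <- v
  u
}

#' Simulate a complete trial
#'
#' Generates treated and control trap layouts and networks, session dates,
#' a BYM2 field on the treated network, counts (control: intensity
#' `lambda_i`; treated: `lambda_i * (theta_i exp(u_j) + theta_floor)` per
#' session, Poisson or negative binomial), a weekly release log, and the
#' stored truth.
#'
#' @param config a [trial_config()].
#' @return list of class `"synthetic_trial"`: `records` (`trap_records`
#'   for both sites), `releases` (`release_events`), `network_treated`,
#'   `network_control`, `truth` (field `u`, `theta_true`, seeds, config).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  seeds <- derive_seeds(config$seed, 6)
  layout_t <- generate_layout(config$J_treated, seed = seeds[1])
  layout_c <- generate_layout(config$J_control, seed = seeds[2])
  net_t <- build_trap_network(data.frame(trap_id = paste0("T", seq_len(config$J_treated)),
                                         x = layout_t[, 1], y = layout_t[, 2]),
                              attr(layout_t, "boundary"))
  net_c <- build_trap_network(data.frame(trap_id = paste0("C", seq_len(config$J_control)),
                                         x = layout_c[, 1], y = layout_c[, 2]),
                              attr(layout_c, "boundary"))
  u <- simulate_bym2_field(net_t, config$sigma_u, config$phi, seed = seeds[3])
  # center on the exponential scale: mean_j exp(u_j) = 1, so the site-level
  # relative density of the generated trial equals theta_true exactly
  u_c <- as.numeric(u) - log(mean(exp(as.numeric(u))))

  scheme <- config$scheme
  I <- length(scheme$period_lengths)
  session_dates <- lapply(seq_len(I), function(i) {
    span <- scheme$period_lengths[i]
    offs <- floor(seq(0, span - 1, length.out = config$sessions_per_period))
    scheme$breaks[i] + unique(offs)
  })

  draw_counts <- function(mu, n, seed) {
    set.seed(seed %% .Machine$integer.max)
    if (is.finite(config$dispersion))
      rnbinom(n, size = config$dispersion, mu = mu)
    else rpois(n, mu)
  }

  grid <- function(ids, site, zone, mu_fun, seed) {
    rows <- list()
    for (i in seq_len(I)) for (dt in as.list(session_dates[[i]])) {
      rows[[length(rows) + 1]] <- data.frame(
        trap_id = ids, site_id = site, zone = zone,
        species = config$species, stage = config$stage,
        date = as.Date(dt, origin = "1970-01-01"),
        mu = mu_fun(i), stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    df$count <- draw_counts(df$mu, nrow(df), seed)
    df$mu <- NULL
    df
  }
  ctrl <- grid(paste0("C", seq_len(config$J_control)), "site_control", "control",
               function(i) rep(config$lambda[i], config$J_control), seeds[4])
  trt <- grid(paste0("T", seq_len(config$J_treated)), "site_treated", "treated",
              function(i) config$lambda[i] *
                (config$theta_true[i] * exp(u_c) + config$theta_floor), seeds[5])
  records <- trap_records(rbind(ctrl, trt))

  release_dates <- seq(scheme$breaks[1], scheme$breaks[I + 1] - 1, by = 7)
  releases <- release_events(data.frame(
    date = release_dates, site_id = "site_treated",
    n_males = rep(2700L * config$J_treated, length(release_dates)),  # ~2700/ha/week at 1 trap/ha
    boosted = TRUE))

  structure(list(records = records, releases = releases,
                 network_treated = net_t, network_control = net_c,
                 truth = list(u = as.numeric(u), u_centered = u_c,
                              w_star = attr(u, "w_star"),
                              v = attr(u, "v"), theta_true = config$theta_true,
                              lambda = config$lambda, seeds = seeds,
                              config = config)),
            class = "synthetic_trial")
}
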