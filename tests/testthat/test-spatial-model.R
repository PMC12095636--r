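make_spec <- function(net, y, E, periods = rep(1, length(y))) {
  obs <- data.frame(trap_id = rep(net$traps$trap_id, length.out = length(y)),
                    period = periods, n_sessions = 1, y = y,
                    E_period = E, E = E, theta_defined = TRUE,
                    theta_obs = y / E)
  sit_model_spec(obs, net)
}

test_that("the likelihood term equals a brute-force sum of Poisson log-pmfs", {
  net <- two_trap_network()
  y <- c(3, 0, 5); E <- c(4, 2, 6)
  spec <- make_spec(net, y, E, periods = c(1, 1, 1))
  lp <- log_posterior(list(b = 0), spec, components = TRUE)
  brute <- sum(dpois(y, E, log = TRUE)) + sum(lfactorial(y))
  expect_equal(unname(lp["loglik"]), brute, tolerance = 1e-12)
  # shifting the intercept changes the likelihood exactly as the pmf does
  lp2 <- log_posterior(list(b = 0.7), spec, components = TRUE)
  brute2 <- sum(dpois(y, E * exp(0.7), log = TRUE)) + sum(lfactorial(y))
  expect_equal(unname(lp2["loglik"]), brute2, tolerance = 1e-12)
})

test_that("the likelihood is maximized at the closed-form Poisson intercept", {
  net <- two_trap_network()
  y <- c(7, 2); E <- c(5, 4)
  spec <- make_spec(net, y, E)
  ll <- function(b1) log_posterior(list(b = b1), spec, components = TRUE)["loglik"]
  opt <- optimize(ll, c(-3, 3), maximum = TRUE)
  expect_equal(opt$maximum, log(sum(y) / sum(E)), tolerance = 1e-4)
})

test_that("the posterior stays finite for all-zero counts", {
  net <- two_trap_network()
  spec <- make_spec(net, c(0, 0), c(5, 5))
  expect_true(is.finite(log_posterior(list(b = -10), spec)))
})

test_that("with no spatial effect the posterior matches the conjugate Gamma-Poisson oracle", {
  set.seed(5)
  net <- build_trap_network(generate_layout(10, seed = 3))
  E <- rep(10, 10); y <- rpois(10, 8)
  spec <- make_spec(net, y, E)
  fit <- fit_spatial_model(spec, chains = 2, iter = 6000, warmup = 1000,
                           seed = 2, spatial = FALSE)
  th <- fitted_theta(fit)
  # with a flat-ish prior, exp(b1) | y ~ Gamma(sum(y), sum(E)) to high accuracy
  expect_equal(th$mean, sum(y) / sum(E), tolerance = 0.02)
  expect_equal(sd(attr(th, "draws")), sqrt(sum(y)) / sum(E), tolerance = 0.1)
})

test_that("the sampler agrees with dense numerical integration on a 2-trap problem", {
  net <- two_trap_network()
  y <- c(3, 7); E <- c(5, 5)
  spec <- make_spec(net, y, E)

  # oracle: integrate the posterior over (b1, sigma, v1, v2) on a dense
  # grid, with phi = 0 so the field is pure white noise
  rate <- -log(0.01)
  b1g <- seq(-2.5, 2.5, length.out = 101)
  sgg <- seq(0.005, 2.2, length.out = 56)
  vg <- seq(-4.5, 4.5, length.out = 61)
  tot <- 0; acc <- 0
  lpb <- -0.5 * b1g^2 / 100
  lpv <- -0.5 * vg^2
  for (s in sgg) {
    eta <- outer(b1g, s * vg, `+`)
    ll1 <- y[1] * eta - E[1] * exp(eta)
    ll2 <- y[2] * eta - E[2] * exp(eta)
    ethet <- exp(eta)
    for (i in seq_along(b1g)) {
      W <- exp(outer(ll1[i, ] + lpv, ll2[i, ] + lpv, `+`) + lpb[i] - rate * s)
      TH <- 0.5 * outer(ethet[i, ], ethet[i, ], `+`)
      tot <- tot + sum(W)
      acc <- acc + sum(W * TH)
    }
  }
  oracle <- acc / tot

  fit <- fit_spatial_model(spec, chains = 2, iter = 20000, warmup = 2000,
                           seed = 3, fix_phi = 0)
  expect_equal(fitted_theta(fit)$mean, oracle, tolerance = 0.005)
})

test_that("identical data and seed give bitwise-identical draws", {
  net <- two_trap_network()
  spec <- make_spec(net, c(4, 6), c(5, 5))
  f1 <- suppressWarnings(fit_spatial_model(spec, chains = 2, iter = 1500,
                                           warmup = 500, seed = 99))
  f2 <- suppressWarnings(fit_spatial_model(spec, chains = 2, iter = 1500,
                                           warmup = 500, seed = 99))
  expect_identical(f1$draws, f2$draws)
})

test_that("every stored draw keeps the structured field summed to zero", {
  trial <- simulate_trial(trial_config(J_treated = 12, J_control = 8, seed = 4))
  obs <- standardize_observations(trial$records, spain_scheme(),
                                  "albopictus", "egg")
  spec <- sit_model_spec(obs, trial$network_treated)
  fit <- suppressWarnings(fit_spatial_model(spec, chains = 1, iter = 1500,
                                            warmup = 500, seed = 5))
  expect_lt(max(abs(fit$draws$w_sum)), 1e-8)
})

test_that("site-level theta is the average of exponentiated predictors", {
  # all linear-predictor components zero -> theta = 1 in every draw
  f0 <- fake_fit(b_draws = matrix(0, 10, 1), u_draws = matrix(0, 10, 3),
                 periods = 1, trap_ids = c("a", "b", "c"))
  th0 <- fitted_theta(f0)
  expect_equal(attr(th0, "draws"), matrix(1, 10, 1), ignore_attr = TRUE)
  # J = 2, u = (log 2, -log 2), b = 0 -> theta = (2 + 0.5) / 2 = 1.25
  f1 <- fake_fit(b_draws = matrix(0, 5, 1),
                 u_draws = matrix(rep(c(log(2), -log(2)), each = 5), 5, 2),
                 periods = 1, trap_ids = c("a", "b"))
  expect_equal(fitted_theta(f1)$mean, 1.25, tolerance = 1e-12)
  # trap level exposes the per-trap exponentiated predictor
  tl <- fitted_theta(f1, "trap_by_period")
  expect_equal(tl$mean, c(2, 0.5), tolerance = 1e-12)
})

test_that("adding a constant to the offsets shifts the intercept, not theta", {
  net <- two_trap_network()
  y <- c(3, 7); E <- c(5, 5)
  spec1 <- make_spec(net, y, E)
  spec2 <- make_spec(net, y, E * exp(1))  # offset + 1
  # eta is identical when the intercept absorbs the offset shift, so the
  # likelihood (and hence fitted theta) is exactly unchanged
  lp1 <- log_posterior(list(b = 0.4), spec1, components = TRUE)
  lp2 <- log_posterior(list(b = 0.4 - 1), spec2, components = TRUE)
  expect_equal(unname(lp1["loglik"]), unname(lp2["loglik"]), tolerance = 1e-9)
})

test_that("goodness of fit returns exact Pearson residuals", {
  X <- matrix(1, 2, 1)
  obs <- data.frame(trap_id = c("a", "b"), period = 1)
  f <- fake_fit(b_draws = matrix(0, 4, 1), u_draws = matrix(0, 4, 2),
                periods = 1, trap_ids = c("a", "b"),
                y = c(1, 4), offset = c(0, 0), X = X, trap_index = c(1, 2),
                obs = obs)
  g <- goodness_of_fit(f)
  expect_equal(g$mu_hat, c(1, 1))
  expect_equal(g$pearson, c(0, 3))   # (1-1)/1 and (4-1)/1
})

test_that("well-specified synthetic data leaves centered residuals", {
  trial <- simulate_trial(trial_config(J_treated = 15, J_control = 10, seed = 6))
  obs <- standardize_observations(trial$records, spain_scheme(),
                                  "albopictus", "egg")
  spec <- sit_model_spec(obs, trial$network_treated)
  fit <- suppressWarnings(fit_spatial_model(spec, chains = 2, iter = 3000,
                                            warmup = 1000, seed = 6))
  g <- goodness_of_fit(fit)
  expect_lt(abs(mean(g$pearson)), 3 / sqrt(nrow(g)))
})

test_that("the PC prior on phi is calibrated and proper", {
  net <- build_trap_network(generate_layout(10, seed = 14))
  pg <- pc_prior_phi(net$basis$zprec, u = 0.5, alpha = 2/3)
  f <- exp(pg$logdens)
  w <- diff(pg$grid)
  total <- sum((f[-1] + f[-length(f)]) / 2 * w)
  expect_equal(total, 1, tolerance = 1e-6)
  below <- pg$grid <= 0.5
  mass_below <- sum((f[which(below)[-sum(below)]] + f[which(below)[-1]]) / 2 *
                      diff(pg$grid[below]))
  expect_equal(mass_below, 2/3, tolerance = 0.01)
  # the sigma prior tail probability matches its calibration by construction
  rate <- boostsit:::.sigma_pc_rate(1, 0.01)
  expect_equal(exp(-rate * 1), 0.01, tolerance = 1e-12)
})

test_that("a degenerate design or foreign traps are rejected", {
  net <- two_trap_network()
  obs <- data.frame(trap_id = "nope", period = 1, n_sessions = 1, y = 1,
                    E_period = 1, E = 1, theta_defined = TRUE, theta_obs = 1)
  expect_error(sit_model_spec(obs, net), "absent")
  obs0 <- data.frame(trap_id = net$traps$trap_id[1], period = 1, n_sessions = 1,
                     y = 1, E_period = 0, E = 0, theta_defined = FALSE,
                     theta_obs = NA)
  expect_error(sit_model_spec(obs0, net), "positive")
})
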