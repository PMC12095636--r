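test_that("dates map into the trial period schemes", {
  lr <- la_reunion_scheme()
  expect_equal(assign_period(as.Date("2021-03-04"), lr), 1L)
  expect_equal(assign_period(as.Date("2021-04-04"), lr), 2L)  # 31 days after start
  expect_equal(assign_period(as.Date("2021-04-03"), lr), 1L)  # last day of period 1
  es <- spain_scheme()
  expect_equal(assign_period(as.Date("2021-06-01"), es), 1L)
  expect_true(is.na(assign_period(as.Date("2021-05-31"), es)))
  expect_true(is.na(assign_period(as.Date("2022-01-01"), es)))
})

test_that("periods partition the scheme window", {
  sch <- la_reunion_scheme()
  days <- seq(sch$breaks[1], sch$breaks[length(sch$breaks)] - 1, by = 1)
  idx <- assign_period(days, sch)
  expect_false(anyNA(idx))
  expect_equal(as.numeric(table(idx)), sch$period_lengths)
})

test_that("expected density is the mean control count per session", {
  sch <- spain_scheme()
  rec <- make_records("C1", "ctrl", "control",
                      as.Date(c("2021-06-02", "2021-06-10", "2021-06-20")),
                      c(2, 4, 6))
  expect_equal(expected_density(rec, 1, sch, "albopictus", "egg"), 4)
  rec0 <- make_records("C1", "ctrl", "control", as.Date("2021-06-02"), 0)
  expect_equal(expected_density(rec0, 1, sch, "albopictus", "egg"), 0)
  expect_error(expected_density(rec, 3, sch, "albopictus", "egg"),
               "no control sessions")
})

test_that("the control-site mean concentrates on the generating intensity", {
  sch <- spain_scheme()
  set.seed(31)
  dates <- as.Date("2021-06-01") + 0:19
  rec <- make_records("C1", "ctrl", "control", dates, rpois(20, 10))
  E <- expected_density(rec, 1, sch, "albopictus", "egg")
  expect_lt(abs(E - 10), 3 * sqrt(10 / 20))
})

test_that("relative density is y over the effective expectation", {
  expect_equal(relative_density_observed(4, 4), 1)
  expect_equal(relative_density_observed(0, 7), 0)
  expect_equal(relative_density_observed(3, 4 * 1.5), 0.5)
  expect_error(relative_density_observed(3, 0), "undefined")
})

test_that("standardization aggregates sessions and keeps theta per-session", {
  sch <- spain_scheme()
  ctrl <- make_records(c("C1", "C2"), "c", "control",
                       as.Date(c("2021-06-02", "2021-06-12")), rep(5, 4))
  trt <- make_records("T1", "t", "treated",
                      as.Date(c("2021-06-02", "2021-06-12")), c(3, 7))
  obs <- standardize_observations(rbind(ctrl, trt), sch, "albopictus", "egg")
  expect_equal(nrow(obs), 1)
  expect_equal(obs$y, 10)           # summed over 2 sessions
  expect_equal(obs$E, 5 * 2)        # E scaled by the session count
  expect_equal(obs$theta_obs, 1)
  # zero expected density flags theta undefined rather than dividing
  ctrl0 <- make_records(c("C1", "C2"), "c", "control",
                        as.Date(c("2021-06-02", "2021-06-12")), rep(0, 4))
  obs0 <- standardize_observations(rbind(ctrl0, trt), sch, "albopictus", "egg")
  expect_false(obs0$theta_defined)
  expect_true(is.na(obs0$theta_obs))
})

test_that("observed relative density is scale-free in expectation", {
  sch <- spain_scheme()
  mean_theta <- function(mult, seed) {
    set.seed(seed)
    dates <- as.Date("2021-06-01") + seq(0, 33, by = 3)
    ctrl <- make_records(paste0("C", 1:6), "c", "control", dates,
                         rpois(6 * length(dates), 8 * mult))
    trt <- make_records(paste0("T", 1:6), "t", "treated", dates,
                        rpois(6 * length(dates), 8 * mult))
    mean(standardize_observations(rbind(ctrl, trt), sch,
                                  "albopictus", "egg")$theta_obs)
  }
  t1 <- vapply(1:20, function(s) mean_theta(1, s), numeric(1))
  t5 <- vapply(1:20, function(s) mean_theta(5, 100 + s), numeric(1))
  expect_lt(abs(mean(t1) - mean(t5)), 0.05)
})

test_that("with identical sites the mean relative density converges to one", {
  sch <- spain_scheme()
  set.seed(8)
  dates <- as.Date("2021-06-01") + 0:33
  lam <- 12
  ctrl <- make_records(paste0("C", 1:10), "c", "control", dates,
                       rpois(10 * 34, lam))
  trt <- make_records(paste0("T", 1:10), "t", "treated", dates,
                      rpois(10 * 34, lam))
  obs <- standardize_observations(rbind(ctrl, trt), sch, "albopictus", "egg")
  # each site contributes 340 sessions; relative SE of each site mean is
  # 1/sqrt(lam * 340), and theta is their ratio
  se <- sqrt(2) / sqrt(lam * 340)
  expect_lt(abs(mean(obs$theta_obs) - 1), 3 * se)
})

test_that("the baseline ratio model recovers the null and a known ratio", {
  # null: treated mean equals E -> ratio compatible with 1
  set.seed(41)
  E <- runif(120, 4, 9)
  expo <- factor(sample(0:2, 120, TRUE))
  y <- rpois(120, E)
  f <- fit_negbin_baseline(y, expo, E)
  expect_true(f$ci95[1] <= 1 && 1 <= f$ci95[2])
  expect_gt(f$ratio, 0)
  expect_true(f$ci95[1] <= f$ratio && f$ratio <= f$ci95[2])

  # parameter recovery: ratio 2.0, n = 150 sessions, 200 replicates
  hits <- 0L
  for (r in 1:200) {
    set.seed(500 + r)
    E <- runif(150, 3, 8)
    expo <- factor(sample(0:3, 150, TRUE))
    mu <- E * 2.0 * c(1, 0.8, 0.6, 0.5)[as.integer(expo)]
    y <- rnbinom(150, size = 5, mu = mu)
    fr <- suppressWarnings(fit_negbin_baseline(y, expo, E))
    hits <- hits + (fr$ci95[1] <= 2 && 2 <= fr$ci95[2])
  }
  expect_gte(hits / 200, 0.90)
})

test_that("degenerate baseline inputs are rejected", {
  expect_error(fit_negbin_baseline(c(0, 0, 0), factor(c(0, 1, 1)), c(1, 1, 1)),
               "zero")
  expect_error(fit_negbin_baseline(c(1, 2), factor(c(0, 0)), c(1, 1)),
               "exposure levels")
})
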