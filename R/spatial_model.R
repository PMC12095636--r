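#' @name spatial-model
#' @title Bayesian BYM2 spatial Poisson model of relative density
#'
#' @description
#' Counts at treated-site traps are modeled as Poisson with mean
#' `E * theta`, where the log relative density for trap j in exposure
#' period i is `b_1 + b_i x_i + u_j`: an intercept for the reference
#' (first) period, a fixed effect per later period, and a BYM2 spatial
#' random effect `u = sigma_u * (sqrt(phi) w* + sqrt(1 - phi) v)` mixing a
#' scaled intrinsic CAR field `w*` (sum-to-zero) with white noise `v`.
#' Inference is by an adaptive Metropolis-within-Gibbs sampler; the
#' site-level relative density per period is the average of exponentiated
#' linear predictors over the J traps.
NULL

#' Penalized-complexity prior for the BYM2 mixing parameter
#'
#' Builds the PC prior density of `phi` on a grid: the distance from the
#' base model (pure white noise, `phi = 0`) is `d(phi) = sqrt(2 KLD(phi))`
#' where KLD compares `N(0, (1-phi) I + phi Sigma_w*)` against `N(0, I)`
#' using the eigenvalues of the scaled structure covariance; the
#' exponential rate on `d` is calibrated so that `P(phi < u) = alpha`.
#'
#' @param zprec prior precisions of the scaled-field eigen-coefficients
#'   (from a `trap_network`'s `basis$zprec`); their reciprocals are the
#'   nonzero eigenvalues of the scaled structure covariance.
#' @param u,alpha calibration: `P(phi < u) = alpha` (defaults 0.5 and 2/3).
#' @param ngrid grid resolution.
#' @return list with `grid` (phi values) and `logdens` (log density,
#'   normalized on the grid).
#' @export
pc_prior_phi <- function(zprec, u = 0.5, alpha = 2/3, ngrid = 501) {
  gamma <- 1 / zprec                       # eigenvalues of Sigma_w* (sum-to-zero space)
  J <- length(gamma) + 1                   # +1 constant direction with eigenvalue 0
  grid <- seq(1e-4, 1 - 1e-4, length.out = ngrid)
  kld <- vapply(grid, function(phi) {
    ev <- c(1 - phi + phi * gamma, 1 - phi)
    0.5 * (sum(ev) - J - sum(log(ev)))
  }, numeric(1))
  d <- sqrt(2 * pmax(kld, 0))
  dd <- c(diff(d) / diff(grid))
  dd <- pmax(c(dd[1], (dd[-length(dd)] + dd[-1]) / 2, dd[length(dd)]), 1e-12)
  dens_for <- function(lam) lam * exp(-lam * d) * dd
  cdf_at_u <- function(lam) {
    f <- dens_for(lam)
    w <- diff(grid)
    cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * w))
    tot <- cum[length(cum)]
    stats::approx(grid, cum / tot, xout = u)$y
  }
  lam <- tryCatch(
    stats::uniroot(function(l) cdf_at_u(l) - alpha, c(1e-4, 200))$root,
    error = function(e) stats::optimize(function(l) (cdf_at_u(l) - alpha)^2,
                                        c(1e-4, 200))$minimum)
  f <- dens_for(lam)
  w <- diff(grid)
  tot <- sum((f[-1] + f[-length(f)]) / 2 * w)
  list(grid = grid, logdens = log(f / tot), rate = lam)
}

# exponential rate for the PC prior on sigma_u: P(sigma > u) = alpha
.sigma_pc_rate <- function(u, alpha) -log(alpha) / u

#' Model specification for the spatial suppression model
#'
#' @param obs `standardized_obs` data frame (treated site) from
#'   [standardize_observations()]; all rows must have positive effective E.
#' @param network `trap_network` covering the treated site's traps.
#' @param threshold suppression success threshold on the relative-density
#'   scale (default 0.20, i.e. 80% suppression).
#' @param priors list: `sigma_u = c(u, alpha)` for `P(sigma_u > u) = alpha`
#'   (default `c(1, 0.01)`) and `phi = c(u, alpha)` for `P(phi < u) = alpha`
#'   (default `c(0.5, 2/3)`).
#' @return object of class `"sit_model_spec"`.
#' @export
sit_model_spec <- function(obs, network, threshold = 0.20,
                           priors = list(sigma_u = c(1, 0.01), phi = c(0.5, 2/3))) {
  stopifnot(inherits(network, "trap_network"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must lie in (0, 1)")
  obs <- as.data.frame(obs)
  if (any(!obs$theta_defined %||% TRUE) || any(obs$E <= 0))
    stop("all observations must have positive effective expected density")
  tid <- match(as.character(obs$trap_id), network$traps$trap_id)
  if (any(is.na(tid)))
    stop("observations reference traps absent from the network: ",
         paste(unique(obs$trap_id[is.na(tid)]), collapse = ", "))
  periods <- sort(unique(obs$period))
  X <- matrix(1, nrow(obs), 1, dimnames = list(NULL, "intercept"))
  if (length(periods) > 1) {
    ind <- vapply(periods[-1], function(p) as.numeric(obs$period == p),
                  numeric(nrow(obs)))
    X <- cbind(X, ind)
    colnames(X) <- c("intercept", paste0("period", periods[-1]))
  }
  if (qr(X)$rank < ncol(X)) stop("degenerate design: exposure indicators are collinear")
  structure(list(y = as.numeric(obs$y), offset = log(obs$E), X = X,
                 trap_index = tid, periods = periods, network = network,
                 threshold = threshold, priors = priors, obs = obs),
            class = "sit_model_spec")
}

#' Log posterior density of the spatial model (up to a constant)
#'
#' Reference implementation used for validation: Poisson log likelihood
#' plus the BYM2 log prior (intrinsic CAR on the structured field via its
#' eigen-coefficients, standard normal white noise, exponential PC prior on
#' `sigma_u`, gridded PC prior on `phi`, N(0, 10^2) on fixed effects).
#'
#' @param params list with `b` (fixed effects), `z` (structured-field
#'   eigen-coefficients), `v` (white noise), `sigma_u`, `phi`.
#' @param spec a [sit_model_spec()].
#' @param components if `TRUE` return `c(loglik, logprior, total)`.
#' @return scalar log posterior (or named components).
#' @export
log_posterior <- function(params, spec, components = FALSE) {
  basis <- spec$network$basis
  J <- nrow(spec$network$traps)
  b <- params$b
  z <- params$z %||% rep(0, ncol(basis$U))
  v <- params$v %||% rep(0, J)
  sigma <- params$sigma_u %||% 0
  phi <- params$phi %||% 0
  if (sigma < 0) stop("sigma_u must be non-negative")
  wstar <- as.numeric(basis$U %*% z)
  u <- sigma * (sqrt(phi) * wstar + sqrt(1 - phi) * v)
  eta <- spec$offset + as.numeric(spec$X %*% b) + u[spec$trap_index]
  ll <- sum(spec$y * eta - exp(eta))
  if (!is.finite(ll)) stop("non-finite Poisson log likelihood (check offsets/params)")
  lp <- -0.5 * sum(b^2) / 100 -
    0.5 * sum(basis$zprec * z^2) -
    0.5 * sum(v^2)
  if (sigma > 0) {
    rate <- .sigma_pc_rate(spec$priors$sigma_u[1], spec$priors$sigma_u[2])
    lp <- lp + log(rate) - rate * sigma
  }
  if (phi > 0 && phi < 1) {
    pg <- pc_prior_phi(basis$zprec, spec$priors$phi[1], spec$priors$phi[2])
    lp <- lp + stats::approx(pg$grid, pg$logdens, xout = phi, rule = 2)$y
  }
  if (!is.finite(lp)) stop("non-finite log prior (check sigma_u/phi)")
  if (components) c(loglik = ll, logprior = lp, total = ll + lp) else ll + lp
}

#' Fit the spatial suppression model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampling of the BYM2 spatial Poisson
#' model. Runs `chains` chains sequentially (all driven by R's RNG, so a
#' fixed `seed` gives bitwise-identical draws), computes split-Rhat and
#' effective sample sizes for the reported parameters, and attaches a
#' convergence warning when any split-Rhat is 1.05 or more.
#'
#' @param spec a [sit_model_spec()].
#' @param chains,iter,warmup,thin MCMC settings (`iter` includes warmup).
#' @param seed RNG seed.
#' @param spatial set `FALSE` to drop the random effect entirely.
#' @param fix_sigma,fix_phi optionally pin a hyperparameter (mainly for
#'   validation against closed-form oracles).
#' @return object of class `"sit_fit"` with elements `draws` (`b`, `sigma`,
#'   `phi`, `u`, `loglik`, `w_sum`, `chain`), `diagnostics`, `spec`, `mcmc`.
#' @export
fit_spatial_model <- function(spec, chains = 2, iter = 8000, warmup = 2000,
                              thin = 1, seed = 1, spatial = TRUE,
                              fix_sigma = NULL, fix_phi = NULL) {
  stopifnot(inherits(spec, "sit_model_spec"), iter > warmup)
  basis <- spec$network$basis
  J <- nrow(spec$network$traps)
  p <- ncol(spec$X)
  if (!is.null(fix_sigma) && fix_sigma == 0) spatial <- FALSE
  pg <- pc_prior_phi(basis$zprec, spec$priors$phi[1], spec$priors$phi[2])
  rate <- .sigma_pc_rate(spec$priors$sigma_u[1], spec$priors$sigma_u[2])
  set.seed(seed %% .Machine$integer.max)
  out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    b0 <- rnorm(p, 0, 0.5)
    b0[1] <- log(sum(spec$y) / sum(exp(spec$offset))) + rnorm(1, 0, 0.2)
    res <- bym2_mcmc_cpp(spec$y, spec$offset, spec$X,
                         as.integer(spec$trap_index - 1L),
                         basis$U, basis$zprec, rate,
                         pg$grid, pg$logdens,
                         as.integer(iter), as.integer(warmup), as.integer(thin),
                         isTRUE(spatial),
                         if (is.null(fix_sigma)) -1 else fix_sigma,
                         if (is.null(fix_phi)) -1 else fix_phi,
                         b0, rnorm(ncol(basis$U), 0, 0.3), rnorm(J, 0, 0.3),
                         exp(rnorm(1, log(0.3), 0.3)),
                         plogis(rnorm(1, 0, 0.5)))
    res$chain <- rep(ch, nrow(res$b))
    out[[ch]] <- res
  }
  draws <- list(
    b = do.call(rbind, lapply(out, `[[`, "b")),
    u = do.call(rbind, lapply(out, `[[`, "u")),
    sigma = unlist(lapply(out, `[[`, "sigma")),
    phi = unlist(lapply(out, `[[`, "phi")),
    loglik = unlist(lapply(out, `[[`, "loglik")),
    w_sum = unlist(lapply(out, `[[`, "w_sum")),
    chain = unlist(lapply(out, `[[`, "chain"))
  )
  colnames(draws$b) <- colnames(spec$X)
  mon <- draws$b
  if (spatial && is.null(fix_sigma)) mon <- cbind(mon, sigma = draws$sigma)
  if (spatial && is.null(fix_phi)) mon <- cbind(mon, phi = draws$phi)
  rhat <- apply(mon, 2, split_rhat, chain = draws$chain)
  ess <- apply(mon, 2, ess_basic)
  converged <- all(is.finite(rhat)) && all(rhat < 1.05)
  if (!converged)
    warning("convergence warning: max split-Rhat = ", round(max(rhat), 3))
  structure(list(draws = draws,
                 diagnostics = list(rhat = rhat, ess = ess, converged = converged),
                 spec = spec,
                 mcmc = list(chains = chains, iter = iter, warmup = warmup,
                             thin = thin, seed = seed, spatial = spatial)),
            class = "sit_fit")
}

#' Split-Rhat convergence diagnostic
#'
#' @param x draws of one parameter (all chains concatenated).
#' @param chain chain id per draw.
#' @return potential scale reduction factor computed on half-split chains.
#' @export
split_rhat <- function(x, chain) {
  pieces <- unlist(lapply(split(x, chain), function(xc) {
    h <- floor(length(xc) / 2)
    list(xc[seq_len(h)], xc[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(pieces); n <- length(pieces[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(pieces, mean, numeric(1))
  vars <- vapply(pieces, var, numeric(1))
  W <- mean(vars); B <- n * var(means)
  if (W < 1e-12) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via initial positive sequence of autocorrelations
ess_basic <- function(x) {
  n <- length(x)
  if (var(x) < 1e-12) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

# per-draw theta: site-level S x I matrix and trap-level S x J x I array
.theta_draws <- function(fit) {
  spec <- fit$spec
  I <- length(spec$periods)
  J <- nrow(spec$network$traps)
  b <- fit$draws$b; u <- fit$draws$u
  S <- nrow(b)
  trap <- array(NA_real_, dim = c(S, J, I))
  site <- matrix(NA_real_, S, I)
  for (i in seq_len(I)) {
    shift <- b[, 1] + if (i == 1) 0 else b[, i]
    et <- exp(sweep(u, 1, shift, `+`))     # S x J matrix of exp(eta) w/o offset
    trap[, , i] <- et
    site[, i] <- rowMeans(et)
  }
  list(site = site, trap = trap)
}

#' Posterior relative densities
#'
#' Site-level relative density per exposure period is the per-draw average
#' of exponentiated linear predictors over the J traps; trap-level is the
#' per-trap exponentiated predictor. Summaries are posterior means with
#' equal-tailed 95% credible intervals.
#'
#' @param fit a `sit_fit`.
#' @param level `"site_by_period"` or `"trap_by_period"`.
#' @return data frame of estimates with columns `period` (and `trap_id`),
#'   `mean`, `lower`, `upper`; the per-draw values are attached as
#'   attribute `"draws"`.
#' @export
fitted_theta <- function(fit, level = c("site_by_period", "trap_by_period")) {
  level <- match.arg(level)
  td <- .theta_draws(fit)
  periods <- fit$spec$periods
  if (level == "site_by_period") {
    out <- data.frame(period = periods,
                      mean = colMeans(td$site),
                      lower = apply(td$site, 2, quantile, 0.025),
                      upper = apply(td$site, 2, quantile, 0.975))
    rownames(out) <- NULL
    attr(out, "draws") <- td$site
    return(out)
  }
  traps <- fit$spec$network$traps$trap_id
  out <- do.call(rbind, lapply(seq_along(periods), function(i) {
    m <- td$trap[, , i, drop = TRUE]
    data.frame(trap_id = traps, period = periods[i],
               mean = colMeans(m),
               lower = apply(m, 2, quantile, 0.025),
               upper = apply(m, 2, quantile, 0.975))
  }))
  rownames(out) <- NULL
  attr(out, "draws") <- td$trap
  out
}

#' Observed vs fitted means and Pearson residuals
#'
#' @param fit a `sit_fit`.
#' @return data frame per observation: `trap_id`, `period`, `y`, `mu_hat`
#'   (posterior mean fitted value), `pearson` (`(y - mu)/sqrt(mu)`; infinite
#'   residuals are flagged when `mu_hat` is 0 with positive `y`).
#' @export
goodness_of_fit <- function(fit) {
  spec <- fit$spec
  b <- fit$draws$b; u <- fit$draws$u
  eta <- matrix(spec$offset, nrow(b), length(spec$y), byrow = TRUE) +
    b %*% t(spec$X) + u[, spec$trap_index, drop = FALSE]
  mu_hat <- colMeans(exp(eta))
  r <- ifelse(mu_hat > 0, (spec$y - mu_hat) / sqrt(mu_hat),
              ifelse(spec$y > 0, Inf, 0))
  data.frame(trap_id = spec$obs$trap_id, period = spec$obs$period,
             y = spec$y, mu_hat = mu_hat, pearson = r)
}

#' @export
print.sit_fit <- function(x, ...) {
  cat(sprintf("BYM2 spatial Poisson fit: %d chains x %d draws, %d traps, %d periods\n",
              x$mcmc$chains, length(x$draws$sigma) / x$mcmc$chains,
              nrow(x$spec$network$traps), length(x$spec$periods)))
  cat(sprintf("max split-Rhat: %.3f%s\n", max(x$diagnostics$rhat),
              if (x$diagnostics$converged) "" else "  ** convergence warning **"))
  print(fitted_theta(x), digits = 3)
  invisible(x)
}

#' Persist posterior draws as delimited text with a JSON diagnostics sidecar
#'
#' @param fit a `sit_fit`.
#' @param path CSV path for the draws; diagnostics go to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  flat <- data.frame(chain = d$chain, d$b, sigma = d$sigma, phi = d$phi,
                     loglik = d$loglik, check.names = FALSE)
  colnames(d$u) <- paste0("u_", fit$spec$network$traps$trap_id)
  flat <- cbind(flat, d$u)
  utils::write.csv(flat, path, row.names = FALSE)
  jsonlite::write_json(list(rhat = as.list(fit$diagnostics$rhat),
                            ess = as.list(fit$diagnostics$ess),
                            converged = fit$diagnostics$converged,
                            mcmc = fit$mcmc),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
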