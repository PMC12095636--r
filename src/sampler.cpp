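// Metropolis-within-Gibbs sampler for the BYM2 spatial Poisson model of
// relative density:
//   y_n ~ Poisson(mu_n),  log mu_n = offset_n + x_n' b + u_{trap(n)}
//   u = sigma * ( sqrt(phi) * w* + sqrt(1 - phi) * v )
// with w* = U z the scaled intrinsic CAR field expressed in the eigenbasis
// of the precision restricted to the sum-to-zero subspace (prior precision
// of z_i is zprec_i), v iid standard normal, an exponential (PC) prior on
// sigma and a gridded PC prior on phi.  All randomness goes through R's
// RNG so runs are reproducible from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double pois_loglik(const arma::vec& y, const arma::vec& eta) {
  return arma::dot(y, eta) - arma::accu(arma::exp(eta));
}

// linear interpolation of a log-density grid (clamped at the ends)
static double grid_interp(double x, const arma::vec& gx, const arma::vec& gy) {
  const int K = gx.n_elem;
  if (x <= gx[0]) return gy[0];
  if (x >= gx[K - 1]) return gy[K - 1];
  int lo = 0, hi = K - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (gx[mid] <= x) lo = mid; else hi = mid; }
  double t = (x - gx[lo]) / (gx[hi] - gx[lo]);
  return gy[lo] + t * (gy[hi] - gy[lo]);
}

struct AdaptiveScale {
  double ls;        // log step size
  explicit AdaptiveScale(double init = 0.3) : ls(std::log(init)) {}
  double sd() const { return std::exp(ls); }
  void adapt(bool accepted, double rate) {
    ls += rate * ((accepted ? 1.0 : 0.0) - 0.44);
    if (ls < -12.0) ls = -12.0;
    if (ls > 4.0) ls = 4.0;
  }
};

// [[Rcpp::export]]
List bym2_mcmc_cpp(const arma::vec& y, const arma::vec& offset, const arma::mat& X,
                   const arma::uvec& trap,            // 0-based trap index per obs
                   const arma::mat& U,                // J x m eigenbasis
                   const arma::vec& zprec,            // prior precision of z
                   const double lambda_sigma,
                   const arma::vec& phi_grid, const arma::vec& phi_logdens,
                   const int iter, const int warmup, const int thin,
                   const bool spatial,
                   const double sigma_fix, const double phi_fix, // < 0 => sampled
                   const arma::vec& b_init, const arma::vec& z_init,
                   const arma::vec& v_init,
                   const double sigma_init, const double phi_init) {
  const int p = X.n_cols, m = U.n_cols, J = U.n_rows;

  arma::vec b = b_init;
  arma::vec z = z_init, v = v_init;
  const bool sample_sigma = spatial && sigma_fix < 0.0;
  const bool sample_phi   = spatial && phi_fix < 0.0;
  double sigma = spatial ? (sample_sigma ? sigma_init : sigma_fix) : 0.0;
  double phi   = spatial ? (sample_phi ? phi_init : phi_fix) : 0.0;
  double ls = std::log(std::max(sigma, 1e-6));
  double lphi = std::log(std::max(phi, 1e-9)) - std::log(std::max(1.0 - phi, 1e-9));

  arma::vec wstar = U * z;
  arma::vec u(J, arma::fill::zeros);
  if (spatial) u = sigma * (std::sqrt(phi) * wstar + std::sqrt(1.0 - phi) * v);
  arma::vec eta = offset + X * b + u.elem(trap);
  double ll = pois_loglik(y, eta);

  std::vector<AdaptiveScale> sc_b(p, AdaptiveScale(0.3)),
      sc_z(m, AdaptiveScale(0.5)), sc_v(J, AdaptiveScale(0.5));
  AdaptiveScale sc_ls(0.3), sc_lphi(0.8), sc_ls2(0.5);
  std::vector<AdaptiveScale> sc_d(m, AdaptiveScale(0.7));

  const int S = (iter - warmup) / thin;
  arma::mat b_draws(S, p), u_draws(S, J);
  arma::vec sigma_draws(S), phi_draws(S), ll_draws(S), wsum_draws(S);

  int stored = 0;
  for (int it = 1; it <= iter; ++it) {
    const bool adapting = it <= warmup;
    const double arate = std::min(0.25, 2.0 / std::sqrt((double) it));

    // fixed effects
    for (int k = 0; k < p; ++k) {
      const double e = sc_b[k].sd() * R::rnorm(0.0, 1.0);
      arma::vec eta_p = eta + e * X.col(k);
      const double ll_p = pois_loglik(y, eta_p);
      const double bp = b[k] + e;
      const double dpr = -0.5 * (bp * bp - b[k] * b[k]) / 100.0; // N(0, 10^2)
      const bool acc = std::log(R::runif(0.0, 1.0)) < (ll_p - ll + dpr);
      if (acc) { b[k] = bp; eta = eta_p; ll = ll_p; }
      if (adapting) sc_b[k].adapt(acc, arate);
    }

    if (spatial) {
      const double sphi = std::sqrt(phi), s1mphi = std::sqrt(1.0 - phi);
      // structured field coefficients
      for (int i = 0; i < m; ++i) {
        const double e = sc_z[i].sd() * R::rnorm(0.0, 1.0);
        arma::vec du = (sigma * sphi * e) * U.col(i);
        arma::vec eta_p = eta + du.elem(trap);
        const double ll_p = pois_loglik(y, eta_p);
        const double zp = z[i] + e;
        const double dpr = -0.5 * zprec[i] * (zp * zp - z[i] * z[i]);
        const bool acc = std::log(R::runif(0.0, 1.0)) < (ll_p - ll + dpr);
        if (acc) { z[i] = zp; wstar += e * U.col(i); u += du; eta = eta_p; ll = ll_p; }
        if (adapting) sc_z[i].adapt(acc, arate);
      }
      // unstructured field
      for (int j = 0; j < J; ++j) {
        const double e = sc_v[j].sd() * R::rnorm(0.0, 1.0);
        const double du = sigma * s1mphi * e;
        arma::vec eta_p = eta;
        for (arma::uword n = 0; n < trap.n_elem; ++n)
          if ((int) trap[n] == j) eta_p[n] += du;
        const double ll_p = pois_loglik(y, eta_p);
        const double vp = v[j] + e;
        const double dpr = -0.5 * (vp * vp - v[j] * v[j]);
        const bool acc = std::log(R::runif(0.0, 1.0)) < (ll_p - ll + dpr);
        if (acc) { v[j] = vp; u[j] += du; eta = eta_p; ll = ll_p; }
        if (adapting) sc_v[j].adapt(acc, arate);
      }
      // decomposition move: exchange structured for unstructured content
      // along directions that leave u (hence the likelihood) unchanged
      if (phi > 1e-12 && phi < 1.0 - 1e-12) {
        const double r = std::sqrt(phi / (1.0 - phi));
        for (int i = 0; i < m; ++i) {
          const double e = sc_d[i].sd() * R::rnorm(0.0, 1.0);
          const double zp = z[i] + e;
          arma::vec v_p = v - (r * e) * U.col(i);
          const double dpr = -0.5 * zprec[i] * (zp * zp - z[i] * z[i]) -
            0.5 * (arma::dot(v_p, v_p) - arma::dot(v, v));
          const bool acc = std::log(R::runif(0.0, 1.0)) < dpr;
          if (acc) { z[i] = zp; wstar += e * U.col(i); v = v_p; }
          if (adapting) sc_d[i].adapt(acc, arate);
        }
      }
      // sigma (log scale), exponential PC prior
      if (sample_sigma) {
        const double e = sc_ls.sd() * R::rnorm(0.0, 1.0);
        const double ls_p = ls + e, sigma_p = std::exp(ls_p);
        arma::vec u_p = (sigma_p / sigma) * u;
        arma::vec du = u_p - u;
        arma::vec eta_p = eta + du.elem(trap);
        const double ll_p = pois_loglik(y, eta_p);
        const double dpr = (-lambda_sigma * sigma_p + ls_p) - (-lambda_sigma * sigma + ls);
        const bool acc = std::log(R::runif(0.0, 1.0)) < (ll_p - ll + dpr);
        if (acc) { ls = ls_p; sigma = sigma_p; u = u_p; eta = eta_p; ll = ll_p; }
        if (adapting) sc_ls.adapt(acc, arate);
      }
      // phi (logit scale), gridded PC prior
      if (sample_phi) {
        const double e = sc_lphi.sd() * R::rnorm(0.0, 1.0);
        const double lphi_p = lphi + e;
        const double phi_p = 1.0 / (1.0 + std::exp(-lphi_p));
        arma::vec u_p = sigma * (std::sqrt(phi_p) * wstar + std::sqrt(1.0 - phi_p) * v);
        arma::vec du = u_p - u;
        arma::vec eta_p = eta + du.elem(trap);
        const double ll_p = pois_loglik(y, eta_p);
        const double pr_p = grid_interp(phi_p, phi_grid, phi_logdens) +
          std::log(phi_p) + std::log(1.0 - phi_p);
        const double pr_c = grid_interp(phi, phi_grid, phi_logdens) +
          std::log(phi) + std::log(1.0 - phi);
        const bool acc = std::log(R::runif(0.0, 1.0)) < (ll_p - ll + pr_p - pr_c);
        if (acc) { lphi = lphi_p; phi = phi_p; u = u_p; eta = eta_p; ll = ll_p; }
        if (adapting) sc_lphi.adapt(acc, arate);
      }
      // interweaved sigma update: along the curve that keeps sigma*z and
      // sigma*v (hence u and the likelihood) fixed, the conditional of
      // sigma is one-dimensional; sample it by gridded independence MH
      if (sample_sigma) {
        const double C = 0.5 * sigma * sigma *
          (arma::dot(zprec, arma::square(z)) + arma::dot(v, v));
        const int K = 301;
        const double ls_lo = std::log(1e-4), ls_hi = std::log(10.0);
        const double h = (ls_hi - ls_lo) / (K - 1);
        // log density in log-sigma: -C/s^2 - (m+J-1) log s - lambda s
        arma::vec lp(K);
        for (int k = 0; k < K; ++k) {
          const double s = std::exp(ls_lo + k * h);
          lp[k] = -C / (s * s) - (m + J - 1) * std::log(s) - lambda_sigma * s;
        }
        lp -= lp.max();
        arma::vec wgt = arma::exp(lp);
        const double tot = arma::accu(wgt);
        double ucum = R::runif(0.0, 1.0) * tot;
        int k = 0; double cum = wgt[0];
        while (cum < ucum && k < K - 1) { ++k; cum += wgt[k]; }
        const double ls_p = ls_lo + k * h + (R::runif(0.0, 1.0) - 0.5) * h;
        const double s_p = std::exp(ls_p);
        auto ldens = [&](double s) {
          return -C / (s * s) - (m + J - 1) * std::log(s) - lambda_sigma * s;
        };
        auto lq = [&](double lsx) {
          int kk = (int) std::lround((lsx - ls_lo) / h);
          if (kk < 0) kk = 0; if (kk > K - 1) kk = K - 1;
          return lp[kk];
        };
        const double lacc = ldens(s_p) - ldens(sigma) + lq(ls) - lq(ls_p);
        if (std::log(R::runif(0.0, 1.0)) < lacc) {
          const double c = sigma / s_p;
          z *= c; v *= c; wstar *= c;
          sigma = s_p; ls = ls_p;
        }
      }
      // interweaved phi update: with sigma*sqrt(phi)*z and
      // sigma*sqrt(1-phi)*v fixed (u unchanged), the conditional of phi is
      // one-dimensional; gridded independence MH on the prior grid
      if (sample_phi) {
        const double A = 0.5 * phi * arma::dot(zprec, arma::square(z));
        const double B = 0.5 * (1.0 - phi) * arma::dot(v, v);
        const int K = phi_grid.n_elem;
        const double h = phi_grid[1] - phi_grid[0];
        auto ldens = [&](double t, double lpr) {
          return -A / t - B / (1.0 - t) - 0.5 * m * std::log(t) -
            0.5 * J * std::log(1.0 - t) + lpr;
        };
        arma::vec lp(K);
        for (int k = 0; k < K; ++k) lp[k] = ldens(phi_grid[k], phi_logdens[k]);
        lp -= lp.max();
        arma::vec wgt = arma::exp(lp);
        const double tot = arma::accu(wgt);
        double ucum = R::runif(0.0, 1.0) * tot;
        int k = 0; double cum = wgt[0];
        while (cum < ucum && k < K - 1) { ++k; cum += wgt[k]; }
        double t_p = phi_grid[k] + (R::runif(0.0, 1.0) - 0.5) * h;
        if (t_p < phi_grid[0]) t_p = phi_grid[0];
        if (t_p > phi_grid[K - 1]) t_p = phi_grid[K - 1];
        auto lq = [&](double t) {
          int kk = (int) std::lround((t - phi_grid[0]) / h);
          if (kk < 0) kk = 0; if (kk > K - 1) kk = K - 1;
          return lp[kk];
        };
        const double lacc = ldens(t_p, grid_interp(t_p, phi_grid, phi_logdens)) -
          ldens(phi, grid_interp(phi, phi_grid, phi_logdens)) + lq(phi) - lq(t_p);
        if (std::log(R::runif(0.0, 1.0)) < lacc) {
          const double cz = std::sqrt(phi / t_p), cv = std::sqrt((1.0 - phi) / (1.0 - t_p));
          z *= cz; v *= cv; wstar *= cz;
          phi = t_p;
          lphi = std::log(phi) - std::log(1.0 - phi);
        }
      }
      // shift move: trade intercept against the free mean of the
      // unstructured field (likelihood-invariant direction)
      if (sample_sigma || sigma > 0.0) {
        const double denom = sigma * std::sqrt(1.0 - phi);
        if (denom > 1e-12) {
          const double e = sc_ls2.sd() * R::rnorm(0.0, 1.0);
          const double c = e / denom;
          const double b1p = b[0] + e;
          const double dpr_b = -0.5 * (b1p * b1p - b[0] * b[0]) / 100.0;
          const double dpr_v = -0.5 * (arma::accu(arma::square(v - c)) -
                                       arma::accu(arma::square(v)));
          const bool acc = std::log(R::runif(0.0, 1.0)) < (dpr_b + dpr_v);
          if (acc) { b[0] = b1p; v -= c; u -= e; }
          if (adapting) sc_ls2.adapt(acc, arate);
        }
      }
    }

    if (it > warmup && (it - warmup) % thin == 0 && stored < S) {
      b_draws.row(stored) = b.t();
      u_draws.row(stored) = u.t();
      sigma_draws[stored] = sigma;
      phi_draws[stored] = phi;
      ll_draws[stored] = ll;
      wsum_draws[stored] = arma::accu(wstar);
      ++stored;
    }
  }

  return List::create(_["b"] = b_draws, _["u"] = u_draws,
                      _["sigma"] = sigma_draws, _["phi"] = phi_draws,
                      _["loglik"] = ll_draws, _["w_sum"] = wsum_draws);
}
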