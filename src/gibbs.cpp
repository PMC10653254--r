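// Compiled Gibbs engine for the outcome-selection mixed model.
//
// This file mirrors R/sweep.R (gibbs_chain_r) call for call: same update
// order, same sequence of draws from R's RNG, and long-double accumulation
// of sums (matching R's sum()). Both engines therefore produce identical
// chains from the same seed, which a test asserts. Keep the two in sync.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double VAR_FLOOR = 1e-10;

static inline double ldnorm(double x, double mean, double v) {
  if (v < VAR_FLOOR) v = VAR_FLOOR;
  double d = x - mean;
  return -0.5 * std::log(2.0 * M_PI * v) - d * d / (2.0 * v);
}

// Neal (2003) slice sampler with stepping out; width 1, cap 50 per side.
template <class F>
static double slice_sample_log(double x0, F logf, double w = 1.0,
                               int max_steps = 50) {
  double ly = logf(x0) + std::log(R::unif_rand());
  double u = R::unif_rand();
  double L = x0 - w * u;
  double Rr = L + w;
  int s = 0;
  while (s < max_steps && logf(L) > ly) { L -= w; ++s; }
  s = 0;
  while (s < max_steps && logf(Rr) > ly) { Rr += w; ++s; }
  for (;;) {
    double x1 = L + R::unif_rand() * (Rr - L);
    if (logf(x1) > ly) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
}

// Michael, Schucany & Haas (1976) inverse-Gaussian sampler.
static double rinvgauss1(double mu, double lambda) {
  double z = R::norm_rand();
  double yv = z * z;
  double x = mu + mu * mu * yv / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * yv + mu * mu * yv * yv);
  double u = R::unif_rand();
  return (u <= mu / (mu + x)) ? x : mu * mu / x;
}

// [[Rcpp::export]]
List gibbs_chain_cpp(List dat, List pr, List init, int burn, int iters,
                     int thin, bool geweke) {
  NumericVector y = clone(as<NumericVector>(dat["y"]));
  IntegerVector jj = dat["jj"];
  IntegerVector pp = dat["pp"];
  NumericVector e = dat["e"];
  NumericMatrix Z = dat["Z"];
  const int n = as<int>(dat["n"]);
  const int K = as<int>(dat["K"]);
  const int q = as<int>(dat["q"]);
  const int m = as<int>(dat["m"]);

  const int variant = as<int>(pr["variant"]);
  const bool scaled = as<int>(pr["spike_type"]) == 0;
  const double cc = as<double>(pr["c"]);
  const double g1 = as<double>(pr["g1"]);
  NumericVector pi_k = pr["pi"];
  const double mu_m0 = as<double>(pr["mu_m0"]), mu_s0sq = as<double>(pr["mu_s0sq"]);
  const double tau_a = as<double>(pr["tau_a"]), tau_bsq = as<double>(pr["tau_bsq"]);
  const double sig_a = as<double>(pr["sig_a"]), sig_bsq = as<double>(pr["sig_bsq"]);
  const double sigr_a = as<double>(pr["sigr_a"]), sigr_bsq = as<double>(pr["sigr_bsq"]);
  const double nu_m = as<double>(pr["nu_m"]), nu_v = as<double>(pr["nu_v"]);
  const double gam_m = as<double>(pr["gam_m"]), gam_v = as<double>(pr["gam_v"]);

  std::vector<double> beta = as<std::vector<double>>(init["beta"]);
  std::vector<int> ind = as<std::vector<int>>(init["ind"]);
  double mu = as<double>(init["mu"]);
  double tau = as<double>(init["tau"]);
  std::vector<double> nu = as<std::vector<double>>(init["nu"]);
  NumericMatrix gamma_in = init["gamma"];
  NumericMatrix gamma(K, q);
  for (int l = 0; l < q; ++l)
    for (int k = 0; k < K; ++k) gamma(k, l) = gamma_in(k, l);
  std::vector<double> alpha = as<std::vector<double>>(init["alpha"]);
  std::vector<double> sigma = as<std::vector<double>>(init["sigma"]);
  double sigma_r = as<double>(init["sigma_r"]);
  std::vector<double> s = as<std::vector<double>>(init["s"]);

  std::vector<std::vector<int>> rows_k(K), rows_j(n);
  for (int i = 0; i < m; ++i) {
    rows_k[pp[i] - 1].push_back(i);
    rows_j[jj[i] - 1].push_back(i);
  }

  auto zdot = [&](int i, int k) {
    double zd = 0.0;
    for (int l = 0; l < q; ++l) zd += gamma(k, l) * Z(i, l);
    return zd;
  };
  auto spike_var = [&]() { return scaled ? tau * tau / cc : g1; };

  const int n_ret = iters / thin;
  const int ncols = 2 * K + 2 + K + K * q + n + K + 1;
  NumericMatrix draws(n_ret, ncols);
  int ret = 0;
  const int total = burn + iters;

  for (int sweep = 1; sweep <= total; ++sweep) {
    if (geweke) {
      for (int i = 0; i < m; ++i) {
        int k = pp[i] - 1;
        double mean_i = nu[k] + alpha[jj[i] - 1] + beta[k] * e[i] + zdot(i, k);
        y[i] = R::rnorm(mean_i, sigma[k]);
      }
    }
    // beta_k (Laplace: plus its latent scale)
    for (int k = 0; k < K; ++k) {
      double s2 = sigma[k] * sigma[k];
      long double sw = 0.0L, swx = 0.0L;
      for (int i : rows_k[k]) {
        double r = y[i] - nu[k] - alpha[jj[i] - 1] - zdot(i, k);
        sw += e[i] * e[i] / s2;
        swx += e[i] * r / s2;
      }
      double pm, pv;
      if (variant == 3) { pm = 0.0; pv = s[k]; }
      else if (ind[k] == 1) { pm = mu; pv = tau * tau; }
      else { pm = 0.0; pv = spike_var(); }
      double V = 1.0 / ((double)sw + 1.0 / pv);
      beta[k] = R::rnorm(V * ((double)swx + pm / pv), std::sqrt(V));
      if (variant == 3) {
        double ab = std::fabs(beta[k]); if (ab < 1e-8) ab = 1e-8;
        s[k] = 1.0 / rinvgauss1(1.0 / ab, 1.0);
      }
    }
    // indicators
    if (variant <= 1) {
      double vsp = spike_var();
      for (int k = 0; k < K; ++k) {
        double la = std::log(pi_k[k]) + ldnorm(beta[k], mu, tau * tau);
        double lb = std::log1p(-pi_k[k]) + ldnorm(beta[k], 0.0, vsp);
        double p1 = 1.0 / (1.0 + std::exp(lb - la));
        ind[k] = (R::unif_rand() < p1) ? 1 : 0;
      }
    }
    // slab mean
    if (variant == 0 || variant == 2) {
      long double sb = 0.0L;
      int n1 = 0;
      for (int k = 0; k < K; ++k) if (ind[k] == 1) { sb += beta[k]; ++n1; }
      double tau2 = tau * tau;  // matches mu_fc_params: length(sel)/tau^2
      double sw = (double)n1 / tau2;
      double swx = (double)sb / tau2;
      double V = 1.0 / (sw + 1.0 / mu_s0sq);
      mu = R::rnorm(V * (swx + mu_m0 / mu_s0sq), std::sqrt(V));
    }
    // nu_k and gamma_k
    for (int k = 0; k < K; ++k) {
      double s2 = sigma[k] * sigma[k];
      int mk = (int)rows_k[k].size();
      long double sx = 0.0L;
      for (int i : rows_k[k]) {
        double r = y[i] - alpha[jj[i] - 1] - beta[k] * e[i] - zdot(i, k);
        sx += r / s2;
      }
      double V = 1.0 / ((double)mk / s2 + 1.0 / nu_v);
      nu[k] = R::rnorm(V * ((double)sx + nu_m / nu_v), std::sqrt(V));
      for (int l = 0; l < q; ++l) {
        long double sw = 0.0L, swx = 0.0L;
        for (int i : rows_k[k]) {
          double partial = zdot(i, k) - gamma(k, l) * Z(i, l);
          double r = y[i] - nu[k] - alpha[jj[i] - 1] - beta[k] * e[i] - partial;
          double w = Z(i, l);
          sw += w * w / s2;
          swx += w * r / s2;
        }
        double Vg = 1.0 / ((double)sw + 1.0 / gam_v);
        gamma(k, l) = R::rnorm(Vg * ((double)swx + gam_m / gam_v), std::sqrt(Vg));
      }
    }
    // alpha_j
    {
      std::vector<long double> sw(n, 0.0L), sx(n, 0.0L);
      for (int i = 0; i < m; ++i) {
        int k = pp[i] - 1, j = jj[i] - 1;
        double s2 = sigma[k] * sigma[k];
        double r = y[i] - nu[k] - beta[k] * e[i] - zdot(i, k);
        sw[j] += 1.0 / s2;
        sx[j] += r / s2;
      }
      for (int j = 0; j < n; ++j) {
        double P = (double)sw[j] + 1.0 / (sigma_r * sigma_r);
        alpha[j] = R::rnorm((double)sx[j] / P, std::sqrt(1.0 / P));
      }
    }
    // tau
    if (variant <= 2) {
      int n1 = 0;
      long double S1l = 0.0L, S0l = 0.0L;
      for (int k = 0; k < K; ++k) {
        if (ind[k] == 1) { double d = beta[k] - mu; S1l += d * d; ++n1; }
        else { S0l += beta[k] * beta[k]; }
      }
      int n0 = K - n1;
      double S1 = (double)S1l, S0 = (double)S0l;
      auto logf = [&](double th) {
        double t2 = std::exp(2.0 * th);
        double ll = -(double)n1 * th - S1 / (2.0 * t2);
        if (scaled) ll = ll - (double)n0 * (th - 0.5 * std::log(cc)) -
          S0 * cc / (2.0 * t2);
        return ll + ldnorm(th, tau_a, tau_bsq);
      };
      tau = std::exp(slice_sample_log(std::log(tau), logf));
    }
    // sigma_k
    for (int k = 0; k < K; ++k) {
      long double SSEl = 0.0L;
      for (int i : rows_k[k]) {
        double r = y[i] - nu[k] - alpha[jj[i] - 1] - beta[k] * e[i] - zdot(i, k);
        SSEl += r * r;
      }
      double SSE = (double)SSEl;
      double mk = (double)rows_k[k].size();
      auto logf = [&](double th) {
        return -mk * th - SSE / (2.0 * std::exp(2.0 * th)) +
          ldnorm(th, sig_a, sig_bsq);
      };
      sigma[k] = std::exp(slice_sample_log(std::log(sigma[k]), logf));
    }
    // sigma_r
    {
      long double SSl = 0.0L;
      for (int j = 0; j < n; ++j) SSl += alpha[j] * alpha[j];
      double SS = (double)SSl;
      auto logf = [&](double th) {
        return -(double)n * th - SS / (2.0 * std::exp(2.0 * th)) +
          ldnorm(th, sigr_a, sigr_bsq);
      };
      sigma_r = std::exp(slice_sample_log(std::log(sigma_r), logf));
    }

    // finiteness check, then record
    bool ok = std::isfinite(mu) && std::isfinite(tau) && std::isfinite(sigma_r);
    for (int k = 0; k < K && ok; ++k)
      ok = std::isfinite(beta[k]) && std::isfinite(nu[k]) && std::isfinite(sigma[k]);
    for (int j = 0; j < n && ok; ++j) ok = std::isfinite(alpha[j]);
    for (int l = 0; l < q && ok; ++l)
      for (int k = 0; k < K && ok; ++k) ok = std::isfinite(gamma(k, l));
    if (!ok) stop("non-finite parameter state at sweep %d", sweep);

    if (sweep > burn && (sweep - burn) % thin == 0) {
      int c = 0;
      for (int k = 0; k < K; ++k) draws(ret, c++) = beta[k];
      for (int k = 0; k < K; ++k) draws(ret, c++) = ind[k];
      draws(ret, c++) = mu;
      draws(ret, c++) = tau;
      for (int k = 0; k < K; ++k) draws(ret, c++) = nu[k];
      for (int l = 0; l < q; ++l)
        for (int k = 0; k < K; ++k) draws(ret, c++) = gamma(k, l);
      for (int j = 0; j < n; ++j) draws(ret, c++) = alpha[j];
      for (int k = 0; k < K; ++k) draws(ret, c++) = sigma[k];
      draws(ret, c++) = sigma_r;
      ++ret;
    }
    if (sweep % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws, _["y_final"] = y);
}
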