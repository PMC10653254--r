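# Full conditionals for the Gibbs sweep -------------------------------------
#
# Reference (pure R) versions of every update used by the sampler. The C++
# engine in src/gibbs.cpp mirrors these call for call — including the order
# of random-number draws — so that both engines produce identical chains
# from the same seed. Variance floor 1e-10 inside density evaluations.

VAR_FLOOR <- 1e-10

ldnorm <- function(x, mean, varv) {
  varv <- max(varv, VAR_FLOOR)
  -0.5 * log(2 * pi * varv) - (x - mean)^2 / (2 * varv)
}

spike_variance <- function(pr, tau) {
  if (pr$spike_type == 0L) tau^2 / pr$c else pr$g1
}

# Conjugate-normal posterior from precision-weighted sufficient statistics:
# likelihood contributes sum_w = sum w_i^2/s2_i and sum_wx = sum w_i r_i/s2_i,
# prior N(m0, v0). Returns c(mean, var).
fc_normal <- function(sum_w, sum_wx, m0, v0) {
  v <- 1 / (sum_w + 1 / v0)
  c(mean = v * (sum_wx + m0 / v0), var = v)
}

# beta_k | rest: rows R_k with residuals net of nu_k, alpha, gamma'z and the
# exposure as regressor; prior N(mu, tau^2) when I_k = 1, N(0, v_spike)
# otherwise (Laplace variant: N(0, s_k) given the latent scale).
beta_fc_params <- function(r, e, sigma_k, prior_mean, prior_var) {
  s2 <- sigma_k^2
  fc_normal(sum(e * e / s2), sum(e * r / s2), prior_mean, prior_var)
}

# P(I_k = 1 | beta_k, mu, tau): Bernoulli with the slab/spike density ratio,
# computed in log space.
indicator_prob <- function(beta_k, mu, tau, v_spike, pi_k) {
  if (pi_k < 0 || pi_k > 1) stop("pi_k must lie in [0, 1]")
  la <- log(pi_k) + ldnorm(beta_k, mu, tau^2)
  lb <- log1p(-pi_k) + ldnorm(beta_k, 0, v_spike)
  d <- lb - la
  if (is.nan(d)) stop("indicator probability undefined (pi_k = 0 and 1?)")
  1 / (1 + exp(d))
}

# mu | rest: conjugate over the slab members S = {k : I_k = 1}; prior
# N(m0, s0^2); empty S falls back to the prior.
mu_fc_params <- function(beta_sel, tau, m0, s0sq) {
  fc_normal(length(beta_sel) / tau^2, sum(beta_sel) / tau^2, m0, s0sq)
}

# alpha_j | rest: conjugate with per-row precisions 1/sigma_{p[i]}^2 and
# prior N(0, sigma_r^2).
alpha_fc_params <- function(r, sigma_rows, sigma_r) {
  fc_normal(sum(1 / sigma_rows^2), sum(r / sigma_rows^2), 0, sigma_r^2)
}

# Slice sampler (Neal 2003) with stepping out, used on the log scale for the
# lognormal-prior scale parameters. Width 1, step-out capped at 50 per side.
slice_sample_log <- function(x0, logf, w = 1, max_steps = 50L) {
  ly <- logf(x0) + log(runif(1))
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  s <- 0L
  while (s < max_steps && logf(L) > ly) { L <- L - w; s <- s + 1L }
  s <- 0L
  while (s < max_steps && logf(R) > ly) { R <- R + w; s <- s + 1L }
  repeat {
    x1 <- L + runif(1) * (R - L)
    if (logf(x1) > ly) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# Inverse-Gaussian sampler (Michael, Schucany & Haas 1976); consumed by the
# Bayesian-LASSO latent-scale update.
rinvgauss1 <- function(mu, lambda) {
  z <- rnorm(1)
  yv <- z * z
  x <- mu + mu * mu * yv / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * yv + mu * mu * yv * yv)
  u <- runif(1)
  if (u <= mu / (mu + x)) x else mu * mu / x
}

# log full conditional of theta = log(tau). Slab members contribute
# N(beta_k; mu, tau^2); with a scaled spike the unselected beta contribute
# N(beta_k; 0, tau^2/c) as well. Prior: theta ~ N(tau_a, tau_bsq).
tau_logf <- function(th, n1, S1, n0, S0, scaled, c, tau_a, tau_bsq) {
  t2 <- exp(2 * th)
  ll <- -n1 * th - S1 / (2 * t2)
  if (scaled) ll <- ll - n0 * (th - 0.5 * log(c)) - S0 * c / (2 * t2)
  ll + ldnorm(th, tau_a, tau_bsq)
}

# log full conditional of theta = log(sigma) given a Gaussian sum of squares
# (m terms, SSE) and lognormal prior N(a, bsq) on theta.
scale_logf <- function(th, m, SSE, a, bsq) {
  -m * th - SSE / (2 * exp(2 * th)) + ldnorm(th, a, bsq)
}

#' Log-likelihood of a stacked panel under the mixed model
#'
#' Computes `sum_i log N(y_i; nu_p\[i\] + alpha_j\[i\] + beta_p\[i\] *
#' exposure_j\[i\] + gamma_p\[i\]' z_j\[i\], sigma_p\[i\]^2)` — the Gaussian
#' likelihood of the stacked observations given a complete parameter state.
#'
#' @param state A list with elements `beta`, `nu` (length-K vectors), `gamma`
#'   (K x q matrix, omitted or zero-column when there are no covariates),
#'   `alpha` (length-n vector), `sigma` (length-K, strictly positive).
#' @param panel An [outcome_panel].
#' @return A single number, the log-likelihood.
#' @export
log_likelihood <- function(state, panel) {
  dat <- panel_data(panel)
  beta <- state$beta; nu <- state$nu; alpha <- state$alpha; sigma <- state$sigma
  stopifnot(length(beta) == dat$K, length(nu) == dat$K,
            length(alpha) == dat$n, length(sigma) == dat$K)
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  gamma <- state$gamma
  if (is.null(gamma)) gamma <- matrix(0, dat$K, dat$q)
  gamma <- matrix(gamma, nrow = dat$K)
  zd <- if (dat$q > 0) rowSums(dat$Z * gamma[dat$pp, , drop = FALSE]) else 0
  mu_i <- nu[dat$pp] + alpha[dat$jj] + beta[dat$pp] * dat$e + zd
  sum(dnorm(dat$y, mu_i, sigma[dat$pp], log = TRUE))
}
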