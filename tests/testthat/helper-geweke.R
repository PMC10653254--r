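# Joint-distribution ("getting it right", Geweke 2004) test machinery.
#
# Successive-conditional simulator: alternate (a) redrawing the data from the
# model given the current parameters and (b) one full Gibbs sweep of the
# posterior kernel. If every update targets its full conditional, the
# stationary marginal of the parameters is exactly the prior, which we can
# also sample iid. Moments of the two samples are compared by z-score.

geweke_panel <- function() {
  # fixed covariates, 4 individuals x 2 outcomes; y is overwritten by the
  # data-redraw step so its initial value is irrelevant
  outcome_panel(data.frame(
    individual_id = rep(1:4, each = 2), outcome_id = rep(1:2, 4),
    y = 0, exposure = rep(c(0.5, -1, 1, 2), each = 2),
    z = rep(c(0.3, -0.7, 1.2, -0.2), each = 2)))
}

# priors kept moderately tight so prior draws stay in a numerically sane
# range; the kernel must be exact for *any* prior setting
geweke_spec <- function(variant, subset_outcomes = NULL) {
  model_spec(variant, spike = spike_scaled(10), pi = 0.5,
             mu_prior = c(0, 1), tau_prior = c(0, 0.25),
             sigma_prior = c(0, 0.25), sigma_r_prior = c(0, 0.25),
             nu_prior = c(0, 1), gamma_prior = c(0, 1),
             subset_outcomes = subset_outcomes)
}

# run the successive-conditional chain with the compiled kernel
geweke_chain <- function(variant, sweeps = 52000, discard = 2000, seed = 1) {
  panel <- geweke_panel()
  spec <- geweke_spec(variant,
                      subset_outcomes = if (variant == "subset") 1L)
  sampling_variant <- variant
  if (variant == "subset") {
    panel <- outsel:::panel_subset(panel, 1L)
    sampling_variant <- "hierarchical"
  }
  dat <- outsel:::panel_data(panel)
  pr <- outsel:::resolve_spec(spec, dat$K, variant = sampling_variant)
  init <- outsel:::init_state(dat, pr)
  set.seed(seed)
  res <- outsel:::gibbs_chain_cpp(dat, pr, init, discard, sweeps - discard,
                                  1L, TRUE)
  colnames(res$draws) <- outsel:::draw_colnames(dat$K, dat$n, dat$q)
  res$draws
}

# iid draws from the prior of the scalar parameters compared below
geweke_prior_draws <- function(variant, N = 200000, seed = 2) {
  set.seed(seed)
  tau <- exp(rnorm(N, 0, 0.5))
  sigma1 <- exp(rnorm(N, 0, 0.5))
  sigma_r <- exp(rnorm(N, 0, 0.5))
  nu1 <- rnorm(N, 0, 1)
  mu <- switch(variant, ssvs_null = rep(0, N), laplace = rep(0, N),
               rnorm(N, 0, 1))
  I1 <- switch(variant,
               ssvs_mean = rbinom(N, 1, 0.5),
               ssvs_null = rbinom(N, 1, 0.5),
               rep(1L, N))
  beta1 <- switch(variant,
    laplace = rexp(N) - rexp(N),  # Laplace(0, 1)
    ifelse(I1 == 1, rnorm(N, mu, tau), rnorm(N, 0, tau / sqrt(10))))
  list(mu = mu, tau = tau, beta.1 = beta1, I.1 = I1, sigma.1 = sigma1,
       sigma_r = sigma_r, nu.1 = nu1)
}

# two-sample z-score on a moment; the successive-conditional sample is
# autocorrelated, so its standard error uses the effective sample size
geweke_z <- function(sc, prior, f = identity) {
  x <- f(sc); y <- f(prior)
  ess <- outsel:::ess_chains(outsel:::split_chains(list(x)))
  if (!is.finite(ess) || ess < 10) ess <- 10
  se2 <- var(x) / ess + var(y) / length(y)
  (mean(x) - mean(y)) / sqrt(se2)
}

geweke_params_for <- function(variant) {
  switch(variant,
    ssvs_mean = c("mu", "tau", "beta.1", "I.1", "sigma.1", "sigma_r", "nu.1"),
    ssvs_null = c("tau", "beta.1", "I.1", "sigma.1", "sigma_r", "nu.1"),
    hierarchical = c("mu", "tau", "beta.1", "sigma.1", "sigma_r", "nu.1"),
    subset = c("mu", "tau", "beta.1", "sigma.1", "sigma_r", "nu.1"),
    laplace = c("beta.1", "sigma.1", "sigma_r", "nu.1"))
}
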