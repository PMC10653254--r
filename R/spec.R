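# Model specification -------------------------------------------------------

#' Spike components for the spike-and-slab prior
#'
#' The two-component mixture prior on the per-outcome exposure coefficient is
#' `p(beta_k | I_k) = (1 - I_k) N(0, v_spike) + I_k N(mu, tau^2)`. The spike
#' variance `v_spike` is either tied to the slab scale, `tau^2 / c`
#' (`spike_scaled`, the recommended form; larger `c` gives sharper separation
#' between "in" and "out" outcomes), or a fixed constant `g1` (`spike_fixed`).
#'
#' @param c Positive scale ratio for the scaled spike (default 100).
#' @param g1 Positive fixed spike variance, e.g. `0.2^2`.
#' @return An object of class `outsel_spike`.
#' @export
spike_scaled <- function(c = 100) {
  stopifnot(is.numeric(c), length(c) == 1, is.finite(c), c > 0)
  structure(list(type = "scaled", c = as.numeric(c)), class = "outsel_spike")
}

#' @rdname spike_scaled
#' @export
spike_fixed <- function(g1) {
  stopifnot(is.numeric(g1), length(g1) == 1, is.finite(g1), g1 > 0)
  structure(list(type = "fixed", g1 = as.numeric(g1)), class = "outsel_spike")
}

#' Specify a model variant and its priors
#'
#' Bundles the prior variant and all hyperparameters for [run_mcmc()].
#' Variants:
#' \describe{
#'   \item{`ssvs_mean`}{the proposed model: spike-and-slab selection with an
#'     unknown slab mean `mu` shared by the selected outcomes.}
#'   \item{`ssvs_null`}{standard spike-and-slab with the slab centred at 0
#'     (`mu` fixed at 0).}
#'   \item{`hierarchical`}{no selection; every `beta_k ~ N(mu, tau^2)`.}
#'   \item{`subset`}{the hierarchical model fitted only to
#'     `subset_outcomes` (the benchmark that uses a known relevant set).}
#'   \item{`laplace`}{shrinkage comparator: independent `Laplace(0, 1)`
#'     priors on `beta_k`, no indicators and no common mean.}
#' }
#'
#' Normal priors are written `c(mean, variance)` and log-normal priors
#' `c(meanlog, varlog)` (variance on the log scale). Defaults reproduce the
#' reference configuration: scaled spike with `c = 100`, `pi = 0.5`,
#' `mu ~ N(0, 100)`, `tau ~ LN(0, 1)`, `sigma_k, sigma_r ~ LN(0, 10)`,
#' `nu_k, gamma_k ~ N(0, 100)`.
#'
#' @param variant Model variant; see Details.
#' @param spike A [spike_scaled()] or [spike_fixed()] object.
#' @param pi Prior inclusion probabilities `P(I_k = 1)`: a scalar (broadcast
#'   to all outcomes) or a length-`K` vector in `[0, 1]`.
#' @param mu_prior,nu_prior,gamma_prior Normal priors, `c(mean, variance)`.
#' @param tau_prior,sigma_prior,sigma_r_prior Log-normal priors,
#'   `c(meanlog, varlog)`.
#' @param subset_outcomes Integer vector of outcome ids; required (non-empty)
#'   when `variant = "subset"`.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("ssvs_mean", spike = spike_scaled(100), pi = 0.5)
model_spec <- function(variant = c("ssvs_mean", "ssvs_null", "hierarchical",
                                   "subset", "laplace"),
                       spike = spike_scaled(100),
                       pi = 0.5,
                       mu_prior = c(mean = 0, var = 100),
                       tau_prior = c(meanlog = 0, varlog = 1),
                       sigma_prior = c(meanlog = 0, varlog = 10),
                       sigma_r_prior = c(meanlog = 0, varlog = 10),
                       nu_prior = c(mean = 0, var = 100),
                       gamma_prior = c(mean = 0, var = 100),
                       subset_outcomes = NULL) {
  variant <- match.arg(variant)
  if (!inherits(spike, "outsel_spike")) stop("`spike` must come from spike_scaled() or spike_fixed()")
  pi <- as.numeric(pi)
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1))
    stop("`pi` must lie in [0, 1]")
  chk2 <- function(p, nm, positive_second = TRUE) {
    p <- as.numeric(p)
    if (length(p) != 2 || any(!is.finite(p))) stop("`", nm, "` must be two finite numbers")
    if (positive_second && p[2] <= 0) stop("`", nm, "` variance must be > 0")
    p
  }
  mu_prior <- chk2(mu_prior, "mu_prior")
  tau_prior <- chk2(tau_prior, "tau_prior")
  sigma_prior <- chk2(sigma_prior, "sigma_prior")
  sigma_r_prior <- chk2(sigma_r_prior, "sigma_r_prior")
  nu_prior <- chk2(nu_prior, "nu_prior")
  gamma_prior <- chk2(gamma_prior, "gamma_prior")
  if (variant == "subset") {
    if (is.null(subset_outcomes) || length(subset_outcomes) == 0)
      stop("variant 'subset' requires a non-empty `subset_outcomes`")
    subset_outcomes <- sort(unique(as.integer(subset_outcomes)))
  } else if (!is.null(subset_outcomes)) {
    warning("`subset_outcomes` ignored for variant '", variant, "'")
    subset_outcomes <- NULL
  }
  structure(list(variant = variant, spike = spike, pi = pi,
                 mu_prior = mu_prior, tau_prior = tau_prior,
                 sigma_prior = sigma_prior, sigma_r_prior = sigma_r_prior,
                 nu_prior = nu_prior, gamma_prior = gamma_prior,
                 subset_outcomes = subset_outcomes),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  sp <- if (x$spike$type == "scaled") sprintf("tau^2/%g", x$spike$c) else
    sprintf("fixed g1 = %g", x$spike$g1)
  cat(sprintf("<model_spec> variant = %s, spike = %s, pi = %s\n",
              x$variant, sp, paste(format(x$pi), collapse = ", ")))
  invisible(x)
}

#' MCMC run configuration
#'
#' @param chains Number of independent chains (chain `i` is seeded with
#'   `seed + i - 1`).
#' @param burn_in Sweeps discarded before retention.
#' @param iterations Post-burn-in sweeps; `floor(iterations / thin)` states
#'   are retained per chain.
#' @param thin Retain every `thin`-th post-burn-in state.
#' @param seed Integer seed; identical seeds and inputs give bit-identical
#'   draws.
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 3L, burn_in = 5000L, iterations = 5000L,
                         thin = 1L, seed = 1L) {
  chains <- as.integer(chains); burn_in <- as.integer(burn_in)
  iterations <- as.integer(iterations); thin <- as.integer(thin)
  seed <- as.integer(seed)
  stopifnot(chains >= 1L, burn_in >= 0L, iterations >= 1L, thin >= 1L,
            iterations >= thin, !is.na(seed))
  structure(list(chains = chains, burn_in = burn_in, iterations = iterations,
                 thin = thin, seed = seed), class = "mcmc_control")
}

variant_code <- function(variant) {
  switch(variant, ssvs_mean = 0L, ssvs_null = 1L, hierarchical = 2L,
         laplace = 3L, stop("no sampler code for variant '", variant, "'"))
}

# Flatten a model_spec into the plain list consumed by both engines.
# `variant` here is the *sampling* variant (subset is reduced to hierarchical
# before this point).
resolve_spec <- function(spec, K, variant = spec$variant) {
  pi <- spec$pi
  if (length(pi) == 1) pi <- rep(pi, K)
  if (length(pi) != K) stop("`pi` must have length 1 or K = ", K)
  list(variant = variant_code(variant),
       spike_type = if (spec$spike$type == "scaled") 0L else 1L,
       c = if (spec$spike$type == "scaled") spec$spike$c else 1.0,
       g1 = if (spec$spike$type == "fixed") spec$spike$g1 else 1.0,
       pi = pi,
       mu_m0 = spec$mu_prior[1], mu_s0sq = spec$mu_prior[2],
       tau_a = spec$tau_prior[1], tau_bsq = spec$tau_prior[2],
       sig_a = spec$sigma_prior[1], sig_bsq = spec$sigma_prior[2],
       sigr_a = spec$sigma_r_prior[1], sigr_bsq = spec$sigma_r_prior[2],
       nu_m = spec$nu_prior[1], nu_v = spec$nu_prior[2],
       gam_m = spec$gamma_prior[1], gam_v = spec$gamma_prior[2])
}
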