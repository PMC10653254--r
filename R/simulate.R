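# Synthetic data ------------------------------------------------------------
#
# Generator for the benchmark design: K outcomes on n individuals, the first
# K1 outcomes truly exposure-sensitive with coefficients clustered around a
# common mean mu_true (coefficient of variation 0.1), and an exposure whose
# level depends on the sign of the confounder z, so that exposure and z are
# positively correlated.

#' Define a simulation scenario
#'
#' @param n Number of individuals (default 100).
#' @param K Number of outcomes (default 20).
#' @param K1 Number of truly exposure-sensitive outcomes (the first `K1`
#'   outcome ids), `0 <= K1 <= K`.
#' @param mu_true True mean exposure effect across the sensitive outcomes
#'   (benchmark settings: -0.1 weak, -3 strong).
#' @param seed Integer seed; the dataset is fully determined by the scenario.
#' @param sigma_r_true SD of the individual random intercept (default 1).
#' @param gamma_sd SD of the per-outcome confounder coefficients
#'   `gamma_k ~ N(0, gamma_sd^2)` (default 1).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n = 100L, K = 20L, K1, mu_true, seed = 1L,
                         sigma_r_true = 1, gamma_sd = 1) {
  n <- as.integer(n); K <- as.integer(K); K1 <- as.integer(K1)
  stopifnot(n >= 2L, K >= 1L, K1 >= 0L, K1 <= K, sigma_r_true > 0,
            gamma_sd >= 0, is.finite(mu_true))
  structure(list(n = n, K = K, K1 = K1, mu_true = as.numeric(mu_true),
                 seed = as.integer(seed), sigma_r_true = sigma_r_true,
                 gamma_sd = gamma_sd),
            class = "sim_scenario")
}

#' Draw the true parameter values for a scenario
#'
#' Uses the current RNG state. Intercepts `nu_k ~ N(0, 1)`; error variances
#' `sigma_k^2 ~ N(1.5, 0.3^2)` truncated below at 0.05; sensitive
#' coefficients `beta_k ~ N(mu_true, 0.01 * mu_true^2)` for the first `K1`
#' outcomes and exactly 0 for the rest; confounder coefficients
#' `gamma_k ~ N(0, gamma_sd^2)`.
#'
#' @param scenario A [sim_scenario()].
#' @return A list of class `sim_truth`: `beta_true`, `relevant`, `nu_true`,
#'   `sigma_true` (error SDs), `gamma_true`, `sigma_r_true`, and (after
#'   [draw_panel()]/[simulate_dataset()]) `alpha_true`.
#' @export
draw_parameters <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  K <- scenario$K; K1 <- scenario$K1
  nu <- rnorm(K, 0, 1)
  sig2 <- numeric(K)
  for (k in seq_len(K)) {
    repeat {
      v <- rnorm(1, 1.5, 0.3)
      if (v > 0.05) break
    }
    sig2[k] <- v
  }
  beta <- numeric(K)
  relevant <- seq_len(K) <= K1
  if (K1 > 0)
    beta[relevant] <- rnorm(K1, scenario$mu_true, 0.1 * abs(scenario$mu_true))
  gamma <- rnorm(K, 0, scenario$gamma_sd)
  structure(list(beta_true = beta, relevant = relevant, nu_true = nu,
                 sigma_true = sqrt(sig2), gamma_true = gamma,
                 sigma_r_true = scenario$sigma_r_true, alpha_true = NULL),
            class = "sim_truth")
}

#' Generate a stacked panel given true parameter values
#'
#' Uses the current RNG state. Per individual: confounder `z_j ~ N(0, 1)`;
#' exposure `~ N(0, 0.5^2)` when `z_j < 0` and `~ N(1, 1)` otherwise (so
#' exposure level tracks the sign of the confounder); random intercept
#' `alpha_j ~ N(0, sigma_r_true^2)`. Per (individual, outcome) cell:
#' `y = nu_k + alpha_j + beta_k * exposure_j + gamma_k * z_j + eps`,
#' `eps ~ N(0, sigma_k^2)`. The panel is complete: `n * K` rows.
#'
#' @param scenario A [sim_scenario()].
#' @param truth A `sim_truth` from [draw_parameters()].
#' @return An [outcome_panel] with the drawn `alpha` attached as attribute
#'   `alpha_true`.
#' @export
draw_panel <- function(scenario, truth) {
  stopifnot(inherits(scenario, "sim_scenario"), inherits(truth, "sim_truth"))
  n <- scenario$n; K <- scenario$K
  z <- rnorm(n)
  expo <- numeric(n)
  low <- z < 0
  expo[low] <- rnorm(sum(low), 0, 0.5)
  expo[!low] <- rnorm(sum(!low), 1, 1)
  alpha <- rnorm(n, 0, truth$sigma_r_true)
  jj <- rep(seq_len(n), each = K)
  pp <- rep(seq_len(K), times = n)
  eps <- rnorm(n * K, 0, truth$sigma_true[pp])
  y <- truth$nu_true[pp] + alpha[jj] + truth$beta_true[pp] * expo[jj] +
    truth$gamma_true[pp] * z[jj] + eps
  pan <- outcome_panel(data.frame(individual_id = jj, outcome_id = pp, y = y,
                                  exposure = expo[jj], z = z[jj]),
                       n = n, K = K)
  attr(pan, "alpha_true") <- alpha
  pan
}

#' Simulate a complete benchmark dataset
#'
#' Seeds the RNG from `scenario$seed`, then composes [draw_parameters()] and
#' [draw_panel()]; the result is fully determined by the scenario.
#'
#' @param scenario A [sim_scenario()].
#' @return A list with elements `panel` (an [outcome_panel] of `n * K` rows)
#'   and `truth` (a `sim_truth` including `alpha_true`).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_scenario(n = 20, K = 5, K1 = 2, mu_true = -3))
#' nrow(sim$panel)  # 100
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  truth <- draw_parameters(scenario)
  panel <- draw_panel(scenario, truth)
  truth$alpha_true <- attr(panel, "alpha_true")
  list(panel = panel, truth = truth)
}
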