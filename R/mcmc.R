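# Posterior sampling --------------------------------------------------------

#' Draw from the posterior of the outcome-selection mixed model
#'
#' Runs a Metropolis-within-Gibbs sampler for the stacked mixed model
#' `y_i = nu_p\[i\] + alpha_j\[i\] + beta_p\[i\] exposure_j\[i\] +
#' gamma_p\[i\]' z_j\[i\] + eps_i` under the prior variant in `spec`.
#' Every normal full conditional (`beta_k`, `mu`, `nu_k`, `gamma_k`,
#' `alpha_j`) is drawn exactly; the scale parameters `tau`, `sigma_k`,
#' `sigma_r` (log-normal priors) use slice sampling on the log scale; the
#' Laplace variant updates `beta_k` through the exponential scale-mixture
#' augmentation. One sweep updates, in order: all `beta_k` (with latent
#' scales for the Laplace variant), all indicators `I_k` (spike-and-slab
#' variants), `mu` (when modelled), all `(nu_k, gamma_k)`, all `alpha_j`,
#' `tau` (when modelled), all `sigma_k`, `sigma_r`.
#'
#' The `subset` variant first restricts the panel to
#' `spec$subset_outcomes` and then runs the hierarchical sampler on the
#' reduced panel; reported outcome ids refer to the original panel.
#'
#' @param panel An [outcome_panel].
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_control()]. Chain `i` is seeded with
#'   `seed + i - 1`; identical inputs and seed give bit-identical draws.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; identical draws, much slower).
#' @return An object of class `outsel_draws`: retained post-burn-in,
#'   post-thinning states for each chain, with the configuration attached.
#' @seealso [summarize_selection()], [convergence_report()], [write_draws()]
#' @export
#' @examples
#' sim <- simulate_dataset(sim_scenario(n = 30, K = 4, K1 = 2, mu_true = -3))
#' fit <- run_mcmc(sim$panel, model_spec("ssvs_mean"),
#'                 mcmc_control(chains = 1, burn_in = 100, iterations = 200))
#' summarize_selection(fit)
run_mcmc <- function(panel, spec, mcmc = mcmc_control(),
                     engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!inherits(spec, "model_spec")) stop("`spec` must be a model_spec()")
  if (!inherits(mcmc, "mcmc_control")) stop("`mcmc` must be an mcmc_control()")
  if (!inherits(panel, "outcome_panel")) panel <- outcome_panel(panel)

  outcome_ids <- seq_len(attr(panel, "K"))
  sampling_variant <- spec$variant
  if (spec$variant == "subset") {
    panel <- panel_subset(panel, spec$subset_outcomes)
    outcome_ids <- attr(panel, "original_outcome_ids")
    sampling_variant <- "hierarchical"
  }
  dat <- panel_data(panel)
  pr <- resolve_spec(spec, dat$K, variant = sampling_variant)
  init <- init_state(dat, pr)

  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + ch - 1L)
    res <- if (engine == "cpp") {
      gibbs_chain_cpp(dat, pr, init, mcmc$burn_in, mcmc$iterations, mcmc$thin,
                      FALSE)
    } else {
      gibbs_chain_r(dat, pr, init, mcmc$burn_in, mcmc$iterations, mcmc$thin)
    }
    dr <- res$draws
    colnames(dr) <- draw_colnames(dat$K, dat$n, dat$q)
    chains[[ch]] <- dr
  }
  structure(list(chains = chains, variant = spec$variant,
                 outcome_ids = outcome_ids, n = dat$n, K = dat$K, q = dat$q,
                 spec = spec, mcmc = mcmc, engine = engine),
            class = "outsel_draws")
}

draw_colnames <- function(K, n, q) {
  gcols <- if (q == 1) paste0("gamma.", seq_len(K)) else if (q > 1)
    as.vector(sapply(seq_len(q), function(l) paste0("gamma", l, ".", seq_len(K))))
  else character()
  c(paste0("beta.", seq_len(K)), paste0("I.", seq_len(K)), "mu", "tau",
    paste0("nu.", seq_len(K)), gcols, paste0("alpha.", seq_len(n)),
    paste0("sigma.", seq_len(K)), "sigma_r")
}

#' @export
print.outsel_draws <- function(x, ...) {
  cat(sprintf(
    "<outsel_draws> variant = %s, %d chain(s) x %d retained states, K = %d, n = %d\n",
    x$variant, length(x$chains), nrow(x$chains[[1]]), x$K, x$n))
  invisible(x)
}

# All chains stacked into one matrix (posterior expectations pool chains).
pooled_draws <- function(draws) {
  stopifnot(inherits(draws, "outsel_draws"))
  do.call(rbind, draws$chains)
}

#' Flatten posterior draws to a data frame
#'
#' One row per retained state, with `chain` and `iter` (post-burn-in sweep
#' number) columns appended — the layout used by [write_draws()].
#'
#' @param x An `outsel_draws` object.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.outsel_draws <- function(x, ...) {
  out <- do.call(rbind, lapply(seq_along(x$chains), function(ch) {
    d <- as.data.frame(x$chains[[ch]])
    d$chain <- ch
    d$iter <- seq_len(nrow(d)) * x$mcmc$thin
    d
  }))
  rownames(out) <- NULL
  out
}

#' Persist posterior draws as delimited text
#'
#' @param draws An `outsel_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  write.csv(as.data.frame(draws), path, row.names = FALSE)
  invisible(path)
}
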