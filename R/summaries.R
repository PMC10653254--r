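# Posterior summaries --------------------------------------------------------

#' Summarize outcome selection from posterior draws
#'
#' Computes, pooling the retained draws of all chains: the posterior
#' inclusion probability of each outcome (`pip`, the posterior mean of
#' `I_k`); the selected set (`pip > threshold`, strict); the conditional
#' coefficient estimate `beta_hat_k` — the mean of `beta_k` over exactly the
#' draws with `I_k = 1` when the outcome is selected and 0 otherwise — and
#' the posterior mean and SD of the common effect `mu` and mean of `tau`.
#'
#' For the no-selection variants the inclusion probability is 1 by
#' construction on every modelled outcome and `beta_hat` is the plain
#' posterior mean; for the Laplace variant "selected" instead flags outcomes
#' whose central 95% credible interval for `beta_k` excludes 0.
#'
#' @param draws An `outsel_draws` object from [run_mcmc()].
#' @param threshold Selection threshold on the inclusion probability
#'   (default 0.5; selection uses strict `>`).
#' @return An object of class `selection_summary`: a list with `outcomes`
#'   (data frame `outcome_id`, `pip`, `selected`, `beta_hat`), `mu_hat`,
#'   `mu_sd`, `tau_hat`, `threshold`, and for spike-and-slab variants
#'   `top_subsets`, the five most frequently sampled indicator vectors.
#' @export
summarize_selection <- function(draws, threshold = 0.5) {
  stopifnot(inherits(draws, "outsel_draws"))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)")
  pool <- pooled_draws(draws)
  K <- draws$K
  bcols <- paste0("beta.", seq_len(K))
  icols <- paste0("I.", seq_len(K))
  ssvs <- draws$variant %in% c("ssvs_mean", "ssvs_null")
  pip <- if (ssvs) colMeans(pool[, icols, drop = FALSE]) else rep(1, K)
  if (draws$variant == "laplace") {
    ci <- apply(pool[, bcols, drop = FALSE], 2, quantile, c(0.025, 0.975))
    selected <- ci[1, ] > 0 | ci[2, ] < 0
  } else {
    selected <- pip > threshold
  }
  beta_hat <- numeric(K)
  for (k in seq_len(K)) {
    if (ssvs) {
      if (selected[k]) {
        keep <- pool[, icols[k]] == 1
        if (!any(keep))
          stop("internal consistency error: outcome ", k,
               " selected but no draw has I_k = 1")
        beta_hat[k] <- mean(pool[keep, bcols[k]])
      } else beta_hat[k] <- 0
    } else {
      beta_hat[k] <- mean(pool[, bcols[k]])
    }
  }
  mu_hat <- mean(pool[, "mu"]); mu_sd <- sd(pool[, "mu"])
  tau_hat <- if (draws$variant == "laplace") NA_real_ else mean(pool[, "tau"])
  top <- NULL
  if (ssvs) {
    keys <- apply(pool[, icols, drop = FALSE], 1, paste, collapse = "")
    tab <- sort(table(keys), decreasing = TRUE)
    top <- utils::head(data.frame(subset = names(tab),
                                  frequency = as.numeric(tab) / nrow(pool)),
                       5L)
    rownames(top) <- NULL
  }
  structure(list(outcomes = data.frame(outcome_id = draws$outcome_ids,
                                       pip = unname(pip),
                                       selected = unname(selected),
                                       beta_hat = unname(beta_hat)),
                 mu_hat = mu_hat, mu_sd = mu_sd, tau_hat = tau_hat,
                 threshold = threshold, top_subsets = top,
                 variant = draws$variant),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("<selection_summary> variant = %s, threshold = %g\n",
              x$variant, x$threshold))
  print(x$outcomes, row.names = FALSE, digits = 3)
  cat(sprintf("mu_hat = %.3f (sd %.3f), tau_hat = %s\n", x$mu_hat, x$mu_sd,
              ifelse(is.na(x$tau_hat), "NA", sprintf("%.3f", x$tau_hat))))
  invisible(x)
}

#' Write a selection summary as delimited text
#'
#' One row per outcome (`outcome_id`, `pip`, `selected`, `beta_hat`) followed
#' by trailing rows for `mu` and `tau`.
#'
#' @param summary A `selection_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "selection_summary"))
  df <- summary$outcomes
  df$outcome_id <- as.character(df$outcome_id)
  df <- rbind(df,
              data.frame(outcome_id = "mu", pip = NA, selected = NA,
                         beta_hat = summary$mu_hat),
              data.frame(outcome_id = "tau", pip = NA, selected = NA,
                         beta_hat = summary$tau_hat))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Mean squared error of coefficient estimates
#'
#' `MSE = (1/K) * sum_k (beta_hat_k - beta_true_k)^2`.
#'
#' @param beta_hat,beta_true Numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
#' @examples
#' coefficient_mse(c(1, 0), c(0, 0))  # 0.5
coefficient_mse <- function(beta_hat, beta_true) {
  if (length(beta_hat) != length(beta_true))
    stop("`beta_hat` and `beta_true` must have equal length")
  mean((beta_hat - beta_true)^2)
}

#' Selection counts against a known truth
#'
#' @param selected Logical vector: outcomes flagged as exposure-sensitive.
#' @param truth Logical vector of the same length: truly sensitive outcomes.
#' @return Named numeric vector `n_selected`, `n_correct`,
#'   `n_false_positive`; `n_selected = n_correct + n_false_positive` always.
#' @export
detection_counts <- function(selected, truth) {
  if (length(selected) != length(truth))
    stop("`selected` and `truth` must have equal length")
  selected <- as.logical(selected); truth <- as.logical(truth)
  c(n_selected = sum(selected),
    n_correct = sum(selected & truth),
    n_false_positive = sum(selected & !truth))
}
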