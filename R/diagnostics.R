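# Convergence diagnostics ----------------------------------------------------
#
# Rank-normalized split-Rhat and effective sample size in the style of
# Vehtari et al. (2021): chains are split in half, pooled draws are replaced
# by normal scores, and ESS uses chain-averaged autocovariances with Geyer's
# initial-monotone-sequence truncation.

rank_normalize <- function(x) {
  S <- length(x)
  qnorm((rank(x, ties.method = "average") - 3 / 8) / (S + 1 / 4))
}

split_chains <- function(chains) {
  out <- list()
  for (ch in chains) {
    N <- length(ch)
    h <- N %/% 2
    if (h < 1) next
    out <- c(out, list(ch[seq_len(h)], ch[(N - h + 1):N]))
  }
  out
}

# autocovariance via FFT, biased (divide by N) as used in the ESS estimator
autocov_fft <- function(x) {
  N <- length(x)
  xc <- x - mean(x)
  M <- 2^ceiling(log2(2 * N))
  f <- fft(c(xc, rep(0, M - N)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE)) / M
  ac[seq_len(N)] / N
}

rhat_split <- function(chains) {
  M <- length(chains)
  if (M < 2) return(NA_real_)
  N <- length(chains[[1]])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, var, 0)
  W <- mean(vars)
  B <- N * var(means)
  if (W < 1e-300) return(if (B > 1e-300) Inf else NA_real_)
  sqrt(((N - 1) / N * W + B / N) / W)
}

ess_chains <- function(chains) {
  M <- length(chains)
  N <- length(chains[[1]])
  if (N < 4) return(NA_real_)
  acov <- vapply(chains, autocov_fft, numeric(N))
  mean_acov <- rowMeans(acov)
  W <- mean(vapply(chains, var, 0))
  B <- if (M > 1) N * var(vapply(chains, mean, 0)) else 0
  var_plus <- (N - 1) / N * W + B / N
  if (var_plus < 1e-300) return(NA_real_)
  rho <- 1 - (W - mean_acov) / var_plus  # rho[1] is lag 0
  # Geyer initial positive + monotone sequence over lag pairs (0,1), (2,3), ...
  max_pairs <- (N - 2) %/% 2
  P <- numeric(0)
  for (t in 0:max_pairs) {
    p <- rho[2 * t + 1] + rho[2 * t + 2]
    if (is.na(p) || p <= 0) break
    P <- c(P, p)
  }
  if (length(P) == 0) P <- max(rho[1], 1e-3)
  P <- cummin(P)
  tau_int <- max(-1 + 2 * sum(P), 1e-3)  # = 1 + 2*sum_{t>=1} rho_t
  M * N / tau_int
}

#' Convergence diagnostics for posterior draws
#'
#' Computes rank-normalized split-Rhat and effective sample size for every
#' scalar parameter, pooling information across chains. Parameters that are
#' constant across all draws (e.g. `mu` under the null-slab variant, or an
#' indicator stuck at 1) get `NA` diagnostics rather than a flag.
#'
#' @param draws An `outsel_draws` object.
#' @param rhat_limit Flag parameters with `rhat` above this value
#'   (default 1.01).
#' @return A data frame with columns `param`, `rhat`, `ess`, `flagged`,
#'   carrying the flagged parameter names in attribute `warnings`. With a
#'   single chain `rhat` is `NA` (undefined) and `ess` is still reported.
#' @export
convergence_report <- function(draws, rhat_limit = 1.01) {
  stopifnot(inherits(draws, "outsel_draws"))
  params <- colnames(draws$chains[[1]])
  out <- data.frame(param = params, rhat = NA_real_, ess = NA_real_,
                    flagged = FALSE)
  for (pidx in seq_along(params)) {
    series <- lapply(draws$chains, function(m) as.numeric(m[, pidx]))
    pooled <- unlist(series)
    if (sd(pooled) < 1e-300) next
    rn <- rank_normalize(pooled)
    grp <- factor(rep(seq_along(series), vapply(series, length, 0L)),
                  levels = seq_along(series))
    splits <- split_chains(split(rn, grp))
    if (length(series) >= 2) out$rhat[pidx] <- rhat_split(splits)
    out$ess[pidx] <- ess_chains(splits)
  }
  out$flagged <- !is.na(out$rhat) & out$rhat > rhat_limit
  attr(out, "warnings") <- out$param[out$flagged]
  out
}
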