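# Shared oracles and fixture builders (all fixtures generated in code).

# Posterior moments of a scalar parameter by grid integration of
# exp(loglik(x)) * N(x; prior_mean, prior_var) — the independent check for
# every conjugate full conditional.
grid_posterior <- function(loglik, prior_mean, prior_var, lo, hi, n = 4001) {
  x <- seq(lo, hi, length.out = n)
  lp <- vapply(x, loglik, 0) +
    dnorm(x, prior_mean, sqrt(prior_var), log = TRUE)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  m <- sum(w * x)
  c(mean = m, var = sum(w * (x - m)^2))
}

# small complete panel with one covariate, deterministic given seed
toy_panel <- function(n = 8, K = 3, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  e <- rnorm(n, 0.5, 1)
  df <- expand.grid(individual_id = seq_len(n), outcome_id = seq_len(K))
  df$y <- rnorm(nrow(df))
  df$exposure <- e[df$individual_id]
  df$z <- z[df$individual_id]
  outcome_panel(df, n = n, K = K)
}

# minimal hand-built draws container for summary tests
fake_draws <- function(beta, I = NULL, mu = 0, tau = 1,
                       variant = "ssvs_mean", n = 1, chains = 1) {
  beta <- as.matrix(beta)
  K <- ncol(beta)
  S <- nrow(beta)
  if (is.null(I)) I <- matrix(1, S, K)
  cn <- outsel:::draw_colnames(K, n, 0)
  per <- split(seq_len(S), rep(seq_len(chains), each = ceiling(S / chains),
                               length.out = S))
  ch <- lapply(per, function(idx) {
    m <- matrix(0, length(idx), length(cn), dimnames = list(NULL, cn))
    m[, paste0("beta.", seq_len(K))] <- beta[idx, , drop = FALSE]
    m[, paste0("I.", seq_len(K))] <- I[idx, , drop = FALSE]
    m[, "mu"] <- rep_len(mu, length(idx))
    m[, "tau"] <- rep_len(tau, length(idx))
    m
  })
  structure(list(chains = unname(ch), variant = variant,
                 outcome_ids = seq_len(K), n = n, K = K, q = 0,
                 spec = NULL, mcmc = mcmc_control(chains = chains, seed = 1),
                 engine = "cpp"),
            class = "outsel_draws")
}
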