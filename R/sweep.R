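# Pure-R Gibbs engine --------------------------------------------------------
#
# Reference implementation of the sampler. The compiled engine in
# src/gibbs.cpp mirrors this function call for call (same update order, same
# sequence of random-number draws, long-double accumulation of sums), so both
# engines produce identical chains from the same seed; a test asserts this.
# The R engine exists for auditability and oracle testing; production runs
# use the compiled one.

# Deterministic, data-informed initial state (no RNG):
# beta_k from the per-outcome OLS slope of y on exposure (0 if degenerate);
# (nu_k, gamma_k) from least squares of y - beta_k e on (1, z); sigma_k the
# residual SD floored at 1e-3; alpha = 0; sigma_r = 0.5; tau = sd(beta)
# floored at 0.1; I = 1; mu = mean(beta) (0 for the null-slab and Laplace
# variants); Laplace latent scales s_k = 1.
init_state <- function(dat, pr) {
  K <- dat$K; n <- dat$n; q <- dat$q
  beta <- numeric(K); nu <- numeric(K)
  gamma <- matrix(0, K, max(q, 1))[, seq_len(q), drop = FALSE]
  sigma <- rep(1, K)
  for (k in seq_len(K)) {
    idx <- which(dat$pp == k)
    if (length(idx) == 0) next
    yk <- dat$y[idx]; ek <- dat$e[idx]
    if (length(idx) >= 2 && var(ek) > 1e-12)
      beta[k] <- stats::cov(ek, yk) / var(ek)
    resid0 <- yk - beta[k] * ek
    X <- cbind(1, dat$Z[idx, , drop = FALSE])
    cf <- tryCatch(qr.coef(qr(X), resid0), error = function(e) NULL)
    if (!is.null(cf) && all(is.finite(cf))) {
      nu[k] <- cf[1]
      if (q > 0) gamma[k, ] <- cf[-1]
      res <- resid0 - as.numeric(X %*% cf)
    } else {
      nu[k] <- mean(resid0)
      res <- resid0 - nu[k]
    }
    if (length(idx) >= 2) {
      s <- sd(res)
      sigma[k] <- if (is.finite(s)) max(s, 1e-3) else 1
    }
  }
  tau <- if (K >= 2) max(sd(beta), 0.1) else 0.1
  if (!is.finite(tau)) tau <- 0.1
  mu <- mean(beta)
  if (pr$variant %in% c(1L, 3L)) mu <- 0
  if (pr$variant == 3L) tau <- 1
  list(beta = beta, ind = rep(1L, K), mu = mu, tau = tau, nu = nu,
       gamma = gamma, alpha = numeric(n), sigma = sigma, sigma_r = 0.5,
       s = rep(1, K))
}

gibbs_chain_r <- function(dat, pr, init, burn, iters, thin, geweke = FALSE) {
  y <- dat$y; jj <- dat$jj; pp <- dat$pp; e <- dat$e; Z <- dat$Z
  n <- dat$n; K <- dat$K; q <- dat$q; m <- dat$m
  variant <- pr$variant
  scaled <- pr$spike_type == 0L
  rows_k <- lapply(seq_len(K), function(k) which(pp == k))
  rows_j <- lapply(seq_len(n), function(j) which(jj == j))

  beta <- init$beta; ind <- as.integer(init$ind); mu <- init$mu; tau <- init$tau
  nu <- init$nu; gamma <- matrix(init$gamma, K, q); alpha <- init$alpha
  sigma <- init$sigma; sigma_r <- init$sigma_r; s <- init$s

  zdot <- function(idx, k) {
    zd <- numeric(length(idx))
    for (l in seq_len(q)) zd <- zd + gamma[k, l] * Z[idx, l]
    zd
  }

  n_ret <- (iters %/% thin)
  ncols <- 2L * K + 2L + K + K * q + n + K + 1L
  draws <- matrix(NA_real_, n_ret, ncols)
  ret <- 0L
  total <- burn + iters
  for (sweep in seq_len(total)) {
    # optional joint-distribution-test mode: redraw y from the current state
    if (geweke) {
      for (i in seq_len(m)) {
        k <- pp[i]; zd <- 0
        for (l in seq_len(q)) zd <- zd + gamma[k, l] * Z[i, l]
        mean_i <- nu[k] + alpha[jj[i]] + beta[k] * e[i] + zd
        y[i] <- rnorm(1, mean_i, sigma[k])
      }
    }
    # beta (and, for the Laplace variant, its latent scale)
    for (k in seq_len(K)) {
      idx <- rows_k[[k]]
      s2 <- sigma[k]^2
      r <- y[idx] - nu[k] - alpha[jj[idx]] - zdot(idx, k)
      ek <- e[idx]
      sw <- sum(ek * ek / s2)
      swx <- sum(ek * r / s2)
      if (variant == 3L) { pm <- 0; pv <- s[k] }
      else if (ind[k] == 1L) { pm <- mu; pv <- tau^2 }
      else { pm <- 0; pv <- spike_variance(pr, tau) }
      V <- 1 / (sw + 1 / pv)
      beta[k] <- rnorm(1, V * (swx + pm / pv), sqrt(V))
      if (variant == 3L) {
        ab <- max(abs(beta[k]), 1e-8)
        s[k] <- 1 / rinvgauss1(1 / ab, 1)
      }
    }
    # inclusion indicators
    if (variant <= 1L) {
      vsp <- spike_variance(pr, tau)
      for (k in seq_len(K)) {
        p1 <- indicator_prob(beta[k], mu, tau, vsp, pr$pi[k])
        ind[k] <- as.integer(runif(1) < p1)
      }
    }
    # slab mean
    if (variant == 0L || variant == 2L) {
      sel <- beta[ind == 1L]
      fc <- mu_fc_params(sel, tau, pr$mu_m0, pr$mu_s0sq)
      mu <- rnorm(1, fc[1], sqrt(fc[2]))
    }
    # outcome-specific intercepts and covariate coefficients
    for (k in seq_len(K)) {
      idx <- rows_k[[k]]
      s2 <- sigma[k]^2
      mk <- length(idx)
      r <- y[idx] - alpha[jj[idx]] - beta[k] * e[idx] - zdot(idx, k)
      V <- 1 / (mk / s2 + 1 / pr$nu_v)
      nu[k] <- rnorm(1, V * (sum(r / s2) + pr$nu_m / pr$nu_v), sqrt(V))
      for (l in seq_len(q)) {
        partial <- zdot(idx, k) - gamma[k, l] * Z[idx, l]
        r <- y[idx] - nu[k] - alpha[jj[idx]] - beta[k] * e[idx] - partial
        w <- Z[idx, l]
        sw <- sum(w * w / s2)
        swx <- sum(w * r / s2)
        V <- 1 / (sw + 1 / pr$gam_v)
        gamma[k, l] <- rnorm(1, V * (swx + pr$gam_m / pr$gam_v), sqrt(V))
      }
    }
    # individual random intercepts
    for (j in seq_len(n)) {
      idx <- rows_j[[j]]
      sig_rows <- sigma[pp[idx]]
      r <- numeric(length(idx))
      for (t in seq_along(idx)) {
        i <- idx[t]; k <- pp[i]; zd <- 0
        for (l in seq_len(q)) zd <- zd + gamma[k, l] * Z[i, l]
        r[t] <- y[i] - nu[k] - beta[k] * e[i] - zd
      }
      sw <- sum(1 / sig_rows^2)
      swx <- sum(r / sig_rows^2)
      P <- sw + 1 / sigma_r^2
      alpha[j] <- rnorm(1, swx / P, sqrt(1 / P))
    }
    # tau (slice on the log scale)
    if (variant <= 2L) {
      n1 <- sum(ind == 1L); n0 <- K - n1
      S1 <- sum((beta[ind == 1L] - mu)^2)
      S0 <- sum(beta[ind == 0L]^2)
      logf <- function(th) tau_logf(th, n1, S1, n0, S0, scaled, pr$c,
                                    pr$tau_a, pr$tau_bsq)
      tau <- exp(slice_sample_log(log(tau), logf))
    }
    # outcome error SDs
    for (k in seq_len(K)) {
      idx <- rows_k[[k]]
      r <- y[idx] - nu[k] - alpha[jj[idx]] - beta[k] * e[idx] - zdot(idx, k)
      SSE <- sum(r * r)
      logf <- function(th) scale_logf(th, length(idx), SSE, pr$sig_a, pr$sig_bsq)
      sigma[k] <- exp(slice_sample_log(log(sigma[k]), logf))
    }
    # random-intercept SD
    SSa <- sum(alpha * alpha)
    logf <- function(th) scale_logf(th, n, SSa, pr$sigr_a, pr$sigr_bsq)
    sigma_r <- exp(slice_sample_log(log(sigma_r), logf))

    state_vec <- c(beta, ind, mu, tau, nu, as.numeric(gamma), alpha, sigma, sigma_r)
    if (any(!is.finite(state_vec)))
      stop(sprintf("non-finite parameter state at sweep %d", sweep))
    if (sweep > burn && (sweep - burn) %% thin == 0L) {
      ret <- ret + 1L
      draws[ret, ] <- state_vec
    }
  }
  list(draws = draws, y_final = y)
}
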