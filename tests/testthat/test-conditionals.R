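# Full conditionals against independent numerical-integration oracles.

test_that("beta full conditional matches the conjugate closed form and integration", {
  # single row, e = 1, sigma = 1, residual 3, prior N(0, 1) -> N(1.5, 0.5)
  fc <- outsel:::beta_fc_params(r = 3, e = 1, sigma_k = 1,
                                prior_mean = 0, prior_var = 1)
  expect_equal(unname(fc["mean"]), 1.5)
  expect_equal(unname(fc["var"]), 0.5)
  orc <- grid_posterior(function(b) dnorm(3, b * 1, 1, log = TRUE),
                        0, 1, -6, 9)
  expect_equal(unname(fc), unname(orc), tolerance = 1e-4)

  # randomized small instances
  set.seed(101)
  for (case in 1:5) {
    mrows <- sample(1:6, 1)
    r <- rnorm(mrows, 0, 2); e <- rnorm(mrows); sk <- runif(1, 0.5, 2)
    pm <- rnorm(1); pv <- runif(1, 0.3, 3)
    fc <- outsel:::beta_fc_params(r, e, sk, pm, pv)
    orc <- grid_posterior(function(b) sum(dnorm(r, b * e, sk, log = TRUE)),
                          pm, pv, fc["mean"] - 10 * sqrt(fc["var"]),
                          fc["mean"] + 10 * sqrt(fc["var"]))
    expect_equal(unname(fc), unname(orc), tolerance = 1e-3)
  }
})

test_that("beta conditional falls back to the prior when the outcome has no rows", {
  fc <- outsel:::beta_fc_params(numeric(0), numeric(0), 1.3,
                                prior_mean = -2, prior_var = 4)
  expect_equal(unname(fc), c(-2, 4))
})

test_that("indicator conditional probability is the slab/spike density ratio", {
  # pi = 1 forces inclusion; pi = 0 forces exclusion
  expect_equal(outsel:::indicator_prob(0.4, 0, 1, 0.01, 1), 1)
  expect_equal(outsel:::indicator_prob(0.4, 0, 1, 0.01, 0), 0)
  expect_error(outsel:::indicator_prob(0, 0, 1, 0.01, 1.4), "pi_k")

  # beta = 0, mu = 0, scaled spike: p = 1/(1 + sqrt(c)); 1/11 at c = 100
  for (tau in c(0.3, 1, 2.5)) {
    p <- outsel:::indicator_prob(0, 0, tau, tau^2 / 100, 0.5)
    expect_equal(p, 1 / 11, tolerance = 1e-12)
  }
  # direct density evaluation oracle at a generic point
  beta <- 0.7; mu <- -0.2; tau <- 0.9; vsp <- 0.05; pk <- 0.3
  num <- pk * dnorm(beta, mu, tau)
  den <- num + (1 - pk) * dnorm(beta, 0, sqrt(vsp))
  expect_equal(outsel:::indicator_prob(beta, mu, tau, vsp, pk), num / den,
               tolerance = 1e-12)

  # deep in the slab the probability approaches 1
  expect_gt(outsel:::indicator_prob(-3, -3, 1, 1 / 100, 0.5), 0.999)

  # sharper spikes (larger c) separate more: probability at 0 decreases
  ps <- vapply(c(10, 100, 1000),
               function(cc) outsel:::indicator_prob(0, 0, 1, 1 / cc, 0.5), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("slab-mean full conditional matches closed form, integration and limits", {
  # tau = 1, prior N(0, 100), selected beta = {2, 4} -> N(6/2.01, 1/2.01)
  fc <- outsel:::mu_fc_params(c(2, 4), tau = 1, m0 = 0, s0sq = 100)
  expect_equal(unname(fc["mean"]), 6 / 2.01)
  expect_equal(unname(fc["var"]), 1 / 2.01)
  orc <- grid_posterior(function(m) sum(dnorm(c(2, 4), m, 1, log = TRUE)),
                        0, 100, -10, 16)
  expect_equal(unname(fc), unname(orc), tolerance = 1e-4)

  # empty slab -> prior
  expect_equal(unname(outsel:::mu_fc_params(numeric(0), 2, -1, 9)), c(-1, 9))

  # flat-prior limit -> sample mean of the selected coefficients
  fc2 <- outsel:::mu_fc_params(c(-3.2, -2.8, -3.1), tau = 0.4, m0 = 0,
                               s0sq = 1e10)
  expect_equal(unname(fc2["mean"]), mean(c(-3.2, -2.8, -3.1)),
               tolerance = 1e-6)
})

test_that("random-intercept conditional matches the shrinkage formula and limits", {
  r <- c(0.8, -0.3, 1.1); sig <- rep(1.4, 3); sr <- 0.9
  fc <- outsel:::alpha_fc_params(r, sig, sr)
  Kt <- 3
  shrink <- Kt * sr^2 / (Kt * sr^2 + sig[1]^2) * mean(r)
  expect_equal(unname(fc["mean"]), shrink, tolerance = 1e-12)
  orc <- grid_posterior(function(a) sum(dnorm(r, a, sig, log = TRUE)),
                        0, sr^2, -5, 5)
  expect_equal(unname(fc), unname(orc), tolerance = 1e-4)
  # sigma_r -> 0 pins alpha at 0
  fc0 <- outsel:::alpha_fc_params(r, sig, 1e-8)
  expect_lt(abs(fc0["mean"]), 1e-10)
  expect_lt(fc0["var"], 1e-15)
})

test_that("intercept/covariate conditionals match integration and the WLS limit", {
  set.seed(77)
  y <- rnorm(5, 2, 1); sk <- 1.3
  # nu given everything else: weights 1/sk^2 on each row
  fc <- outsel:::fc_normal(length(y) / sk^2, sum(y) / sk^2, 0, 100)
  orc <- grid_posterior(function(nu) sum(dnorm(y, nu, sk, log = TRUE)),
                        0, 100, -6, 10)
  expect_equal(unname(fc), unname(orc), tolerance = 1e-4)
  # vague-prior limit recovers least squares on the residuals
  z <- rnorm(5); resid <- rnorm(5)
  fcg <- outsel:::fc_normal(sum(z^2) / sk^2, sum(z * resid) / sk^2, 0, 1e12)
  expect_equal(unname(fcg["mean"]), sum(z * resid) / sum(z^2),
               tolerance = 1e-6)
})

test_that("scale full conditional mode sits near the residual RMS under a diffuse prior", {
  set.seed(5)
  r <- rnorm(40, 0, 1.7)
  SSE <- sum(r^2); m <- length(r)
  opt <- optimize(function(th) outsel:::scale_logf(th, m, SSE, 0, 100),
                  c(-5, 5), maximum = TRUE)
  expect_equal(exp(opt$maximum), sqrt(SSE / m), tolerance = 0.01)
})

test_that("tau conditional ignores unselected coefficients when the spike is fixed", {
  th <- 0.3
  a <- outsel:::tau_logf(th, n1 = 3, S1 = 2.2, n0 = 2, S0 = 5,
                         scaled = FALSE, c = 100, tau_a = 0, tau_bsq = 1)
  b <- outsel:::tau_logf(th, n1 = 3, S1 = 2.2, n0 = 2, S0 = 999,
                         scaled = FALSE, c = 100, tau_a = 0, tau_bsq = 1)
  expect_identical(a, b)
  # with a scaled spike the spike sum of squares matters
  a2 <- outsel:::tau_logf(th, 3, 2.2, 2, 5, TRUE, 100, 0, 1)
  b2 <- outsel:::tau_logf(th, 3, 2.2, 2, 999, TRUE, 100, 0, 1)
  expect_false(a2 == b2)
})

test_that("inverse-Gaussian sampler has the right moments", {
  set.seed(404)
  mu <- 1.7; lam <- 2.3
  x <- replicate(40000, outsel:::rinvgauss1(mu, lam))
  expect_equal(mean(x), mu, tolerance = 0.02)
  expect_equal(var(x), mu^3 / lam, tolerance = 0.1)
})

test_that("with no data the Laplace augmentation draws Laplace(0,1) marginals", {
  # alternate beta | s ~ N(0, s) and 1/s | beta ~ IG(1/|beta|, 1):
  # the stationary marginal of beta is Laplace(0, 1) (mean 0, var 2, E|b|=1)
  set.seed(99)
  S <- 30000
  b <- numeric(S); s <- 1
  for (t in seq_len(S)) {
    bt <- rnorm(1, 0, sqrt(s))
    s <- 1 / outsel:::rinvgauss1(1 / max(abs(bt), 1e-8), 1)
    b[t] <- bt
  }
  expect_equal(mean(b), 0, tolerance = 0.05)
  expect_equal(mean(abs(b)), 1, tolerance = 0.05)
  expect_equal(var(b), 2, tolerance = 0.15)
})

test_that("log-likelihood matches a brute-force per-row loop", {
  # single centred row: log N(0; 0, 1)
  p1 <- outcome_panel(data.frame(individual_id = 1, outcome_id = 1, y = 0,
                                 exposure = 0))
  st1 <- list(beta = 0, nu = 0, alpha = 0, sigma = 1)
  expect_equal(log_likelihood(st1, p1), -0.5 * log(2 * pi))
  expect_error(log_likelihood(list(beta = 0, nu = 0, alpha = 0, sigma = -1),
                              p1), "positive")

  pan <- toy_panel(n = 6, K = 3, seed = 8)
  set.seed(12)
  st <- list(beta = rnorm(3), nu = rnorm(3), gamma = matrix(rnorm(3), 3, 1),
             alpha = rnorm(6), sigma = runif(3, 0.5, 2))
  brute <- 0
  for (i in seq_len(nrow(pan))) {
    k <- pan$outcome_id[i]; j <- pan$individual_id[i]
    m <- st$nu[k] + st$alpha[j] + st$beta[k] * pan$exposure[i] +
      st$gamma[k, 1] * pan$z[i]
    brute <- brute + dnorm(pan$y[i], m, st$sigma[k], log = TRUE)
  }
  expect_equal(log_likelihood(st, pan), brute)

  # intercept/random-effect trade-off is invisible on a 1x1 panel
  stA <- list(beta = 0, nu = 2, alpha = -2, sigma = 1)
  expect_equal(log_likelihood(stA, p1), log_likelihood(st1, p1))
})
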