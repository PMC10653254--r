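test_that("identical seeds and inputs give bit-identical draws", {
  sim <- simulate_dataset(sim_scenario(n = 12, K = 3, K1 = 2, mu_true = -3,
                                       seed = 7))
  mc <- mcmc_control(chains = 2, burn_in = 20, iterations = 40, thin = 2,
                     seed = 31)
  f1 <- run_mcmc(sim$panel, model_spec("ssvs_mean"), mc)
  f2 <- run_mcmc(sim$panel, model_spec("ssvs_mean"), mc)
  expect_identical(f1$chains, f2$chains)
  # different seed, different draws
  f3 <- run_mcmc(sim$panel, model_spec("ssvs_mean"),
                 mcmc_control(chains = 2, burn_in = 20, iterations = 40,
                              thin = 2, seed = 32))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("the compiled and reference engines produce identical chains", {
  sim <- simulate_dataset(sim_scenario(n = 9, K = 3, K1 = 2, mu_true = -2,
                                       seed = 19))
  mc <- mcmc_control(chains = 1, burn_in = 10, iterations = 20, thin = 1,
                     seed = 5)
  specs <- list(model_spec("ssvs_mean"),
                model_spec("ssvs_null", spike = spike_fixed(0.2^2)),
                model_spec("hierarchical"),
                model_spec("subset", subset_outcomes = c(1, 3)),
                model_spec("laplace"))
  for (sp in specs) {
    fc <- run_mcmc(sim$panel, sp, mc, engine = "cpp")
    fr <- run_mcmc(sim$panel, sp, mc, engine = "r")
    expect_identical(fc$chains, fr$chains)
  }
})

test_that("retention follows burn-in, iterations and thinning", {
  sim <- simulate_dataset(sim_scenario(n = 6, K = 2, K1 = 1, mu_true = -1,
                                       seed = 3))
  f <- run_mcmc(sim$panel, model_spec("hierarchical"),
                mcmc_control(chains = 2, burn_in = 13, iterations = 25,
                             thin = 4, seed = 2))
  expect_equal(vapply(f$chains, nrow, 0L), c(6L, 6L))  # floor(25/4)
  df <- as.data.frame(f)
  expect_equal(unique(df$chain), 1:2)
  expect_equal(df$iter[df$chain == 1], seq(4, 24, by = 4))
})

test_that("the null-slab variant keeps mu pinned at zero", {
  sim <- simulate_dataset(sim_scenario(n = 10, K = 3, K1 = 2, mu_true = -2,
                                       seed = 13))
  f <- run_mcmc(sim$panel, model_spec("ssvs_null"),
                mcmc_control(chains = 1, burn_in = 30, iterations = 60,
                             seed = 4))
  expect_true(all(f$chains[[1]][, "mu"] == 0))
})

test_that("the subset variant equals the hierarchical sampler on the reduced panel", {
  sim <- simulate_dataset(sim_scenario(n = 10, K = 4, K1 = 2, mu_true = -2,
                                       seed = 29))
  mc <- mcmc_control(chains = 1, burn_in = 15, iterations = 30, seed = 8)
  fs <- run_mcmc(sim$panel, model_spec("subset", subset_outcomes = c(2, 4)),
                 mc)
  fh <- run_mcmc(outsel:::panel_subset(sim$panel, c(2, 4)),
                 model_spec("hierarchical"), mc)
  expect_identical(fs$chains, fh$chains)
  expect_equal(fs$K, 2L)
  expect_equal(fs$outcome_ids, c(2L, 4L))
  expect_equal(summarize_selection(fs)$outcomes$outcome_id, c(2L, 4L))
})

test_that("forcing pi = 1 makes the selection model match the hierarchical one", {
  # with every indicator pinned in the slab the two variants share a
  # posterior; compare pooled moments from moderately long chains
  sim <- simulate_dataset(sim_scenario(n = 25, K = 3, K1 = 3, mu_true = -2,
                                       seed = 55))
  mc <- mcmc_control(chains = 1, burn_in = 500, iterations = 4000, seed = 10)
  fs <- run_mcmc(sim$panel, model_spec("ssvs_mean", pi = 1), mc)
  fh <- run_mcmc(sim$panel, model_spec("hierarchical"), mc)
  expect_true(all(fs$chains[[1]][, paste0("I.", 1:3)] == 1))
  ms <- colMeans(fs$chains[[1]][, c(paste0("beta.", 1:3), "mu", "tau")])
  mh <- colMeans(fh$chains[[1]][, c(paste0("beta.", 1:3), "mu", "tau")])
  expect_equal(ms, mh, tolerance = 0.08)
})

test_that("outcomes with no rows fall back to their prior", {
  # K declared as 3 but outcome 3 never observed: under the hierarchical
  # variant beta_3 | mu, tau ~ N(mu, tau^2) exactly
  df <- data.frame(individual_id = rep(1:30, each = 2),
                   outcome_id = rep(1:2, 30))
  set.seed(2)
  df$exposure <- rep(rnorm(30), each = 2)
  df$y <- rnorm(60) - 2 * df$exposure
  pan <- outcome_panel(df, K = 3)
  f <- run_mcmc(pan, model_spec("hierarchical"),
                mcmc_control(chains = 1, burn_in = 200, iterations = 3000,
                             seed = 6))
  d <- f$chains[[1]]
  resid <- d[, "beta.3"] - d[, "mu"]
  # standardized residuals should be approximately standard normal
  zres <- resid / d[, "tau"]
  expect_equal(mean(zres), 0, tolerance = 0.08)
  expect_equal(var(zres), 1, tolerance = 0.12)
})

test_that("the sampler recovers a strong common effect from synthetic data", {
  sim <- simulate_dataset(sim_scenario(n = 60, K = 6, K1 = 6, mu_true = -3,
                                       seed = 81))
  f <- run_mcmc(sim$panel, model_spec("hierarchical"),
                mcmc_control(chains = 1, burn_in = 500, iterations = 2000,
                             seed = 17))
  s <- summarize_selection(f)
  expect_lt(abs(s$mu_hat - (-3)), 3 * s$mu_sd)
})

test_that("model and control inputs are validated", {
  sim <- simulate_dataset(sim_scenario(n = 6, K = 2, K1 = 1, mu_true = -1,
                                       seed = 1))
  expect_error(model_spec("subset"), "non-empty")
  expect_error(model_spec("ssvs_mean", pi = 1.2), "0, 1")
  expect_error(mcmc_control(iterations = 0), "iterations")
  expect_error(run_mcmc(sim$panel, model_spec("ssvs_mean", pi = c(0.5, 0.5, 0.5)),
                        mcmc_control(chains = 1, burn_in = 1,
                                     iterations = 2, seed = 1)),
               "length 1 or K")
})
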