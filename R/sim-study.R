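# Simulation-study driver ----------------------------------------------------
#
# Orchestrates the benchmark grid: for each (mu_true, K1) cell, simulate
# `replicates` datasets, fit the requested model variants, and average the
# detection counts, coefficient MSE and mu estimates across replicates.

cell_model_spec <- function(variant, truth) {
  if (variant == "subset") {
    rel <- which(truth$relevant)
    model_spec("subset", subset_outcomes = rel)
  } else {
    model_spec(variant)
  }
}

fit_metrics <- function(variant, fit_summary, truth, K) {
  beta_true <- truth$beta_true
  bh <- fit_summary$outcomes$beta_hat
  if (variant == "subset") {
    counts <- c(n_selected = NA_real_, n_correct = NA_real_,
                n_false_positive = NA_real_)
    mse <- NA_real_  # the subset benchmark is scored on mu only
  } else {
    sel <- fit_summary$outcomes$selected
    counts <- detection_counts(sel, truth$relevant)
    mse <- coefficient_mse(bh, beta_true)
  }
  c(counts, mse = mse, mu_hat = fit_summary$mu_hat,
    tau_hat = fit_summary$tau_hat)
}

#' Run one cell of the simulation benchmark
#'
#' Draws the cell's true parameters once (seeded by `scenario$seed`), then
#' simulates `replicates` datasets from those shared parameters (replicate
#' `r` redraws the confounder, exposure, random intercepts and errors under
#' seed `scenario$seed + r`), fits each requested variant, and averages the
#' per-replicate metrics. The `subset` variant is fitted to the *true*
#' relevant set; spike-and-slab variants use the thresholded conditional
#' coefficient estimator for the MSE, the hierarchical variant the plain
#' posterior mean.
#'
#' @param scenario A [sim_scenario()]; its seed is the replicate base seed.
#' @param variants Character vector of [model_spec()] variants.
#' @param replicates Number of simulated datasets (default 10).
#' @param mcmc An [mcmc_control()] applied to every fit (per fit, the chain
#'   seed is the replicate's data seed).
#' @param threshold Selection threshold passed to [summarize_selection()].
#' @param out_dir Optional directory; when given, the per-replicate metrics
#'   are written to `cell_mu<mu>_K1<K1>.csv` there before averaging.
#' @return An object of class `sim_cell`: `scenario`, `per_replicate`
#'   (one row per replicate x variant), `summary` (per variant: metric means
#'   and standard errors `se_* = sd / sqrt(replicates)`; `NA` SEs when
#'   `replicates = 1`), and `failures`.
#' @export
run_cell <- function(scenario, variants = c("ssvs_mean", "ssvs_null",
                                            "hierarchical", "subset"),
                     replicates = 10L, mcmc = mcmc_control(),
                     threshold = 0.5, out_dir = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"), replicates >= 1L)
  set.seed(scenario$seed)
  truth <- draw_parameters(scenario)
  rows <- list()
  failures <- list()
  for (r in seq_len(replicates)) {
    seed_r <- scenario$seed + r
    set.seed(seed_r)
    panel <- draw_panel(scenario, truth)
    sim <- list(panel = panel, truth = truth)
    for (v in variants) {
      rec <- tryCatch({
        spec <- cell_model_spec(v, sim$truth)
        fit <- run_mcmc(sim$panel, spec,
                        mcmc_control(chains = mcmc$chains,
                                     burn_in = mcmc$burn_in,
                                     iterations = mcmc$iterations,
                                     thin = mcmc$thin, seed = seed_r))
        met <- fit_metrics(v, summarize_selection(fit, threshold), sim$truth,
                           scenario$K)
        data.frame(replicate = r, seed = seed_r, variant = v,
                   failed = FALSE, t(met))
      }, error = function(err) {
        failures[[length(failures) + 1]] <<-
          list(replicate = r, variant = v, message = conditionMessage(err))
        data.frame(replicate = r, seed = seed_r, variant = v,
                   failed = TRUE, n_selected = NA_real_, n_correct = NA_real_,
                   n_false_positive = NA_real_, mse = NA_real_,
                   mu_hat = NA_real_, tau_hat = NA_real_)
      })
      rows[[length(rows) + 1]] <- rec
    }
  }
  per_rep <- do.call(rbind, rows)
  rownames(per_rep) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(per_rep, file.path(out_dir, sprintf("cell_mu%g_K1%d.csv",
                                                  scenario$mu_true,
                                                  scenario$K1)),
              row.names = FALSE)
  }
  metr <- c("n_selected", "n_correct", "n_false_positive", "mse", "mu_hat",
            "tau_hat")
  summ <- do.call(rbind, lapply(unique(per_rep$variant), function(v) {
    d <- per_rep[per_rep$variant == v & !per_rep$failed, , drop = FALSE]
    mns <- vapply(metr, function(m) mean(d[[m]]), 0)
    ses <- vapply(metr, function(m) {
      if (nrow(d) < 2) NA_real_ else sd(d[[m]]) / sqrt(nrow(d))
    }, 0)
    names(ses) <- paste0("se_", metr)
    data.frame(mu_true = scenario$mu_true, K1 = scenario$K1, variant = v,
               replicates_used = nrow(d), t(mns), t(ses))
  }))
  rownames(summ) <- NULL
  structure(list(scenario = scenario, per_replicate = per_rep,
                 summary = summ, failures = failures),
            class = "sim_cell")
}

#' @export
print.sim_cell <- function(x, ...) {
  cat(sprintf("<sim_cell> mu_true = %g, K1 = %d, %d replicate(s)\n",
              x$scenario$mu_true, x$scenario$K1,
              max(x$per_replicate$replicate)))
  print(x$summary, row.names = FALSE, digits = 3)
  if (length(x$failures) > 0)
    cat(length(x$failures), "failed fit(s); see $failures\n")
  invisible(x)
}

grid_pick <- function(results, variants, metric, se = FALSE) {
  base <- unique(do.call(rbind, lapply(results, function(cl)
    cl$summary[, c("mu_true", "K1"), drop = FALSE])))
  rownames(base) <- NULL
  for (v in variants) {
    col <- vapply(seq_len(nrow(base)), function(i) {
      val <- NA_real_
      for (cl in results) {
        s <- cl$summary
        hit <- s$mu_true == base$mu_true[i] & s$K1 == base$K1[i] &
          s$variant == v
        if (any(hit)) val <- s[[if (se) paste0("se_", metric) else metric]][hit][1]
      }
      val
    }, 0)
    base[[paste0(if (se) "se_" else "", metric, "_", v)]] <- col
  }
  base
}

#' Run the full simulation benchmark grid
#'
#' Executes the Cartesian product of `mu_values` and `K1_values` (default:
#' weak/strong effect times `K1 = 5, 10, 15` at `n = 100`, `K = 20`) and
#' assembles three summary tables: detection counts for the spike-and-slab
#' variants, coefficient MSE, and the mean-effect estimates with standard
#' errors. Cell failures are recorded and do not halt the grid.
#'
#' @param mu_values,K1_values Grid of true mean effects and relevant-set
#'   sizes.
#' @param variants Variants fitted in every cell.
#' @param replicates Simulated datasets per cell.
#' @param mcmc An [mcmc_control()] for every fit.
#' @param seed Base seed; cell `i` of the grid uses scenario seed
#'   `seed + 1000 * (i - 1)` and replicate `r` within it adds `r`.
#' @param n,K,sigma_r_true,gamma_sd Scenario fields shared by all cells.
#' @param threshold Selection threshold.
#' @param out_dir Optional output directory: per-replicate CSVs, the three
#'   tables (`table_detection.csv`, `table_mse.csv`, `table_mu.csv`) and a
#'   JSON manifest with the resolved configuration and every replicate seed.
#' @return A list of class `sim_grid`: `cells` (list of [run_cell()]
#'   results), `detection`, `mse`, `mu` (data frames).
#' @export
run_grid <- function(mu_values = c(-0.1, -3), K1_values = c(5L, 10L, 15L),
                     variants = c("ssvs_mean", "ssvs_null", "hierarchical",
                                  "subset"),
                     replicates = 10L, mcmc = mcmc_control(), seed = 1L,
                     n = 100L, K = 20L, sigma_r_true = 1, gamma_sd = 1,
                     threshold = 0.5, out_dir = NULL) {
  grid <- expand.grid(K1 = K1_values, mu_true = mu_values)
  cells <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    scen <- sim_scenario(n = n, K = K, K1 = grid$K1[i],
                         mu_true = grid$mu_true[i],
                         seed = seed + 1000L * (i - 1L),
                         sigma_r_true = sigma_r_true, gamma_sd = gamma_sd)
    cells[[i]] <- tryCatch(
      run_cell(scen, variants = variants, replicates = replicates,
               mcmc = mcmc, threshold = threshold, out_dir = out_dir),
      error = function(err) structure(list(scenario = scen,
                                           error = conditionMessage(err)),
                                      class = "sim_cell_failure"))
  }
  ok <- !vapply(cells, inherits, TRUE, "sim_cell_failure")
  res <- cells[ok]
  ssvs_vars <- intersect(variants, c("ssvs_mean", "ssvs_null"))
  detection <- do.call(cbind, c(list(grid_pick(res, ssvs_vars, "n_selected")),
    lapply(c("n_correct", "n_false_positive"), function(m)
      grid_pick(res, ssvs_vars, m)[, -(1:2), drop = FALSE])))
  mse_vars <- intersect(variants, c("ssvs_mean", "ssvs_null", "hierarchical"))
  mse <- grid_pick(res, mse_vars, "mse")
  mu_vars <- intersect(variants, c("ssvs_mean", "hierarchical", "subset"))
  mu <- cbind(grid_pick(res, mu_vars, "mu_hat"),
              grid_pick(res, mu_vars, "mu_hat", se = TRUE)[, -(1:2),
                                                           drop = FALSE])
  out <- structure(list(cells = cells, detection = detection, mse = mse,
                        mu = mu),
                   class = "sim_grid")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(detection, file.path(out_dir, "table_detection.csv"),
              row.names = FALSE)
    write.csv(mse, file.path(out_dir, "table_mse.csv"), row.names = FALSE)
    write.csv(mu, file.path(out_dir, "table_mu.csv"), row.names = FALSE)
    write_grid_manifest(out, mcmc, seed, replicates, variants,
                        file.path(out_dir, "manifest.json"))
  }
  out
}

write_grid_manifest <- function(grid, mcmc, seed, replicates, variants, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    warning("jsonlite not available; manifest not written")
    return(invisible(NULL))
  }
  cells <- lapply(grid$cells, function(cl) {
    sc <- cl$scenario
    list(mu_true = sc$mu_true, K1 = sc$K1, n = sc$n, K = sc$K,
         sigma_r_true = sc$sigma_r_true, gamma_sd = sc$gamma_sd,
         base_seed = sc$seed,
         replicate_seeds = sc$seed + seq_len(replicates),
         failed = inherits(cl, "sim_cell_failure"))
  })
  manifest <- list(package_version = as.character(packageVersion("outsel")),
                   seed = seed, replicates = replicates, variants = variants,
                   mcmc = unclass(mcmc), cells = cells)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.sim_grid <- function(x, ...) {
  cat("<sim_grid>\nMean-effect estimates (SE):\n")
  print(x$mu, row.names = FALSE, digits = 3)
  invisible(x)
}
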