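Package: outsel
Title: Bayesian Outcome Selection for Multiple-Outcome Exposure Studies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which of many correlated outcomes measured on the same
    individuals are sensitive to an exposure, and estimates the mean exposure
    effect across the affected outcomes. Multiple-outcome data are stacked into
    a long-format panel and analysed with a linear mixed model carrying a
    modified stochastic-search-variable-selection (spike-and-slab) prior whose
    slab component has an unknown common mean. Includes Gibbs samplers for the
    proposed prior and several comparators (standard spike-and-slab,
    hierarchical no-selection, subset, and Laplace shrinkage), posterior
    inclusion probabilities and selection summaries, convergence diagnostics,
    a synthetic data generator, and a simulation-study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
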