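# Stacked multiple-outcome panels ------------------------------------------
#
# A panel holds one row per (individual, outcome) pair. With K outcomes per
# individual the exposure-by-outcome interaction covariates
# x_k[i] = exposure[j[i]] * 1(p[i] = k) are never materialised: each row
# activates exactly one of them (the one with k = outcome_id), so the
# exposure column together with outcome_id is the complete sparse design.

#' Construct a stacked outcome panel
#'
#' Builds (and validates) the long-format representation used by all model
#' fitting functions: one row per (individual, outcome) pair with the outcome
#' value `y`, the individual's `exposure`, and zero or more per-individual
#' covariates in columns named `z`, `z_1`, `z_2`, ...
#'
#' @param data A data frame with columns `individual_id`, `outcome_id`, `y`,
#'   `exposure`, and optionally covariate columns named `z` or `z_*`.
#' @param n Number of individuals; defaults to `max(individual_id)`.
#' @param K Number of outcomes; defaults to `max(outcome_id)`.
#'
#' @details Invariants enforced: at most one row per (individual, outcome)
#'   pair; `exposure` and every `z` column constant within an individual;
#'   integer ids within `1..n` and `1..K`. Missing (individual, outcome)
#'   combinations are allowed and simply have no row.
#'
#' @return A data frame of class `outcome_panel` with attributes `n` and `K`.
#' @seealso [stack_outcomes()], [unstack_outcomes()], [standardize_outcomes()]
#' @export
#' @examples
#' pan <- outcome_panel(data.frame(
#'   individual_id = c(1, 1, 2, 2), outcome_id = c(1, 2, 1, 2),
#'   y = rnorm(4), exposure = c(0.3, 0.3, 1.1, 1.1)))
#' attr(pan, "K")
outcome_panel <- function(data, n = NULL, K = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  req <- c("individual_id", "outcome_id", "y", "exposure")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0)
    stop("panel is missing required column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  data$individual_id <- as.integer(data$individual_id)
  data$outcome_id <- as.integer(data$outcome_id)
  if (anyNA(data$individual_id) || anyNA(data$outcome_id))
    stop("individual_id and outcome_id must be integer-valued and non-missing")
  if (any(data$individual_id < 1L) || any(data$outcome_id < 1L))
    stop("individual_id and outcome_id must be >= 1")
  n <- if (is.null(n)) max(data$individual_id, 1L) else as.integer(n)
  K <- if (is.null(K)) max(data$outcome_id, 1L) else as.integer(K)
  if (max(data$individual_id) > n) stop("individual_id exceeds n = ", n)
  if (max(data$outcome_id) > K) stop("outcome_id exceeds K = ", K)
  if (anyDuplicated(data[c("individual_id", "outcome_id")]) > 0)
    stop("duplicate (individual_id, outcome_id) rows in panel")
  zc <- panel_z_cols(data)
  for (cl in c("exposure", zc)) {
    v <- data[[cl]]
    if (!is.numeric(v)) stop("column '", cl, "' must be numeric")
    spread <- tapply(v, data$individual_id, function(x) diff(range(x)))
    if (any(spread > 0, na.rm = TRUE))
      stop("column '", cl, "' varies within an individual; ",
           "exposure and covariates must be individual-level")
  }
  keep <- c(req, zc)
  extra <- attributes(data)[c("outcome_names", "z_names", "individual_ids")]
  data <- data[order(data$individual_id, data$outcome_id), keep, drop = FALSE]
  rownames(data) <- NULL
  out <- structure(data, n = n, K = K, class = c("outcome_panel", "data.frame"))
  for (a in names(extra)) if (!is.null(extra[[a]])) attr(out, a) <- extra[[a]]
  out
}

# covariate columns: "z" alone or "z_<name>"
panel_z_cols <- function(data) {
  grep("^z($|_)", names(data), value = TRUE)
}

#' @export
print.outcome_panel <- function(x, ...) {
  cat(sprintf("<outcome_panel> %d rows, n = %d individuals, K = %d outcomes, %d covariate(s)\n",
              nrow(x), attr(x, "n"), attr(x, "K"), length(panel_z_cols(x))))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Stack a wide multiple-outcomes table into a long panel
#'
#' Converts one-row-per-individual data (one column per outcome) into the
#' stacked one-row-per-(individual, outcome) representation. Outcome ids
#' `1..K` are assigned by position in `outcome_cols`, and that ordering is
#' preserved in every downstream report. Rows whose outcome value is missing
#' are dropped, so the panel has (number of non-missing outcome cells) rows.
#'
#' @param wide Data frame with one row per individual.
#' @param outcome_cols Ordered character vector naming the outcome columns.
#' @param exposure_col Name of the exposure column (default `"exposure"`).
#' @param z_cols Character vector naming covariate columns (default: none).
#' @param id_col Optional name of a column of unique individual ids. When
#'   absent, individuals are numbered by row order.
#'
#' @return An [outcome_panel] with `nrow(wide) * length(outcome_cols)` rows
#'   minus the missing cells.
#' @export
#' @examples
#' w <- data.frame(iq = c(100, 90), memory = c(55, 60), exposure = c(0, 1))
#' stack_outcomes(w, c("iq", "memory"))
stack_outcomes <- function(wide, outcome_cols, exposure_col = "exposure",
                           z_cols = character(), id_col = NULL) {
  if (!is.data.frame(wide)) stop("`wide` must be a data frame")
  if (length(outcome_cols) == 0) stop("`outcome_cols` must name at least one outcome column")
  bad <- setdiff(c(outcome_cols, exposure_col, z_cols, id_col), names(wide))
  if (length(bad) > 0) stop("columns not found in `wide`: ", paste(bad, collapse = ", "))
  n <- nrow(wide)
  if (n == 0) stop("`wide` has no rows")
  ids <- NULL
  if (!is.null(id_col)) {
    ids <- wide[[id_col]]
    if (anyDuplicated(ids) > 0) stop("duplicate individual ids in column '", id_col, "'")
  }
  K <- length(outcome_cols)
  zmat <- wide[z_cols]
  names(zmat) <- if (length(z_cols) == 1 && z_cols == "z") "z" else
    ifelse(grepl("^z($|_)", z_cols), z_cols, paste0("z_", z_cols))
  long <- do.call(rbind, lapply(seq_len(K), function(k) {
    cbind(data.frame(individual_id = seq_len(n), outcome_id = k,
                     y = as.numeric(wide[[outcome_cols[k]]]),
                     exposure = as.numeric(wide[[exposure_col]])),
          zmat)
  }))
  long <- long[!is.na(long$y), , drop = FALSE]
  pan <- outcome_panel(long, n = n, K = K)
  attr(pan, "outcome_names") <- outcome_cols
  attr(pan, "z_names") <- z_cols
  if (!is.null(ids)) attr(pan, "individual_ids") <- ids
  pan
}

#' Unstack a long panel back to a wide table
#'
#' Inverse of [stack_outcomes()] on complete panels. Missing
#' (individual, outcome) combinations become `NA` cells in the wide table.
#'
#' @param panel An [outcome_panel] (or a data frame coercible to one).
#' @return A data frame with one row per individual: `individual_id`,
#'   `exposure`, any covariate columns, then one column per outcome.
#' @export
unstack_outcomes <- function(panel) {
  if (!inherits(panel, "outcome_panel")) panel <- outcome_panel(panel)
  n <- attr(panel, "n"); K <- attr(panel, "K")
  onames <- attr(panel, "outcome_names")
  if (is.null(onames)) onames <- paste0("outcome_", seq_len(K))
  ids <- attr(panel, "individual_ids")
  if (is.null(ids)) ids <- seq_len(n)
  zc <- panel_z_cols(panel)
  ymat <- matrix(NA_real_, n, K, dimnames = list(NULL, onames))
  ymat[cbind(panel$individual_id, panel$outcome_id)] <- panel$y
  wide <- data.frame(individual_id = ids, exposure = NA_real_)
  for (cl in zc) wide[[cl]] <- NA_real_
  first <- !duplicated(panel$individual_id)
  wide$exposure[panel$individual_id[first]] <- panel$exposure[first]
  for (cl in zc) wide[[cl]][panel$individual_id[first]] <- panel[[cl]][first]
  zn <- attr(panel, "z_names")
  if (!is.null(zn) && length(zn) == length(zc)) names(wide)[match(zc, names(wide))] <- zn
  cbind(wide, as.data.frame(ymat))
}

#' Standardize each outcome to mean zero and unit variance
#'
#' Rescales the `y` values of every outcome to sample mean 0 and sample
#' variance 1, the preprocessing used when outcomes are on incommensurate
#' scales. Standardization is an explicit opt-in step: simulated benchmark
#' panels are analysed on their native scale.
#'
#' @param panel An [outcome_panel]; every outcome needs at least two observed
#'   values with nonzero variance.
#' @return The panel with `y` rescaled per outcome, carrying a `scaling`
#'   attribute (data frame with `outcome_id`, `center`, `scale`) for
#'   back-transformation.
#' @export
standardize_outcomes <- function(panel) {
  if (!inherits(panel, "outcome_panel")) panel <- outcome_panel(panel)
  K <- attr(panel, "K")
  sc <- data.frame(outcome_id = seq_len(K), center = NA_real_, scale = NA_real_)
  y <- panel$y
  for (k in seq_len(K)) {
    idx <- which(panel$outcome_id == k)
    if (length(idx) == 0) next
    if (length(idx) < 2)
      stop("outcome ", k, " has fewer than 2 observed values; cannot standardize")
    m <- mean(y[idx]); s <- sd(y[idx])
    if (!is.finite(s) || s < 1e-12)
      stop("outcome ", k, " is constant; cannot standardize")
    y[idx] <- (y[idx] - m) / s
    sc$center[k] <- m; sc$scale[k] <- s
  }
  panel$y <- y
  attr(panel, "scaling") <- sc
  panel
}

#' Read a long-format panel from a CSV file
#'
#' Expects header names `individual_id`, `outcome` (or `outcome_id`), `y`,
#' `exposure`, and zero or more covariate columns named `z` or `z_*`.
#'
#' @param path Path to a delimited text file.
#' @return An [outcome_panel].
#' @export
read_panel <- function(path) {
  df <- read.csv(path)
  if ("outcome" %in% names(df) && !"outcome_id" %in% names(df))
    names(df)[names(df) == "outcome"] <- "outcome_id"
  outcome_panel(df)
}

#' Write a panel to a CSV file
#'
#' @param panel An [outcome_panel].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  names(df)[names(df) == "outcome_id"] <- "outcome"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Restrict a panel to a set of outcome ids, renumbering them 1..K' while
# recording the original ids (used by the subset model variant).
panel_subset <- function(panel, outcomes) {
  if (!inherits(panel, "outcome_panel")) panel <- outcome_panel(panel)
  K <- attr(panel, "K")
  outcomes <- sort(unique(as.integer(outcomes)))
  if (length(outcomes) == 0) stop("`outcomes` must be non-empty")
  if (any(outcomes < 1L | outcomes > K)) stop("`outcomes` out of range 1..", K)
  keep <- panel$outcome_id %in% outcomes
  sub <- as.data.frame(panel)[keep, , drop = FALSE]
  sub$outcome_id <- match(sub$outcome_id, outcomes)
  out <- outcome_panel(sub, n = attr(panel, "n"), K = length(outcomes))
  attr(out, "original_outcome_ids") <- outcomes
  on <- attr(panel, "outcome_names")
  if (!is.null(on)) attr(out, "outcome_names") <- on[outcomes]
  out
}

# Flat arrays consumed by the samplers. jj/pp are 1-based index maps j[i], p[i].
panel_data <- function(panel) {
  if (!inherits(panel, "outcome_panel")) panel <- outcome_panel(panel)
  zc <- panel_z_cols(panel)
  Z <- if (length(zc) > 0) as.matrix(as.data.frame(panel)[zc]) else
    matrix(0, nrow(panel), 0)
  storage.mode(Z) <- "double"
  list(y = as.numeric(panel$y),
       jj = as.integer(panel$individual_id),
       pp = as.integer(panel$outcome_id),
       e = as.numeric(panel$exposure),
       Z = Z,
       n = attr(panel, "n"), K = attr(panel, "K"), q = ncol(Z),
       m = nrow(panel))
}
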