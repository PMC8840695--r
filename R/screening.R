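#' Weighted cross-tabulation of a covariate against a binary outcome
#'
#' Cell counts are sums of sampling weights (exact internally; round only
#' for display). Row percentages are computed within each covariate level
#' across the two outcome columns, as in standard survey frequency tables.
#' Records missing the variable or the outcome are dropped listwise.
#'
#' @param records Validated child records.
#' @param variable Covariate column name.
#' @param outcome Outcome column name (`"anaemic"` or `"stunted"`).
#' @param use_weights Sum sampling weights (TRUE) or raw counts (FALSE).
#' @return A list with `counts` (levels x 2 matrix, columns `yes`/`no`),
#'   `row_pct`, and `n_dropped`.
#' @export
weighted_crosstab <- function(records, variable, outcome, use_weights = TRUE) {
  stopifnot(variable %in% names(records), outcome %in% names(records))
  keep <- !is.na(records[[variable]]) & !is.na(records[[outcome]])
  n_dropped <- sum(!keep)
  df <- records[keep, , drop = FALSE]
  if (nrow(df) == 0) stop("empty table after listwise deletion")
  lv <- if (is.factor(df[[variable]])) levels(droplevels(df[[variable]])) else
    sort(unique(as.character(df[[variable]])))
  if (length(lv) < 2) {
    stop("variable '", variable, "' has a single observed level")
  }
  w <- if (use_weights) df$weight else rep(1, nrow(df))
  counts <- matrix(0, length(lv), 2, dimnames = list(lv, c("yes", "no")))
  fv <- as.character(df[[variable]])
  yv <- df[[outcome]]
  for (i in seq_along(lv)) {
    sel <- fv == lv[i]
    counts[i, "yes"] <- sum(w[sel & yv == 1])
    counts[i, "no"] <- sum(w[sel & yv == 0])
  }
  row_pct <- counts / rowSums(counts) * 100
  list(counts = counts, row_pct = row_pct, n_dropped = n_dropped)
}

#' Pearson chi-square test on an L x 2 contingency table
#'
#' Pearson chi-square without continuity correction, df = L - 1 for a
#' binary outcome. Works on weighted (non-integer) counts; note that using
#' summed weights without a design-effect correction is not design-based
#' inference.
#'
#' @param counts Numeric L x 2 matrix of (weighted) counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi2_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2, nrow(counts) >= 2, all(counts >= 0))
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) {
    stop("expected cell count of zero; merge sparse categories before testing")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Univariate screening of covariates against both outcomes
#'
#' Cross-tabulates every candidate covariate against each outcome, applies
#' the Pearson chi-square test, and retains a variable when `p < alpha`
#' (strict) for that outcome. A variable enters the joint model if retained
#' for either outcome (union rule).
#'
#' @param records Validated child records carrying both outcomes.
#' @param codebook A [codebook()].
#' @param variables Candidate covariates (default: all codebook variables
#'   present in `records`).
#' @param alpha Screening level (default 0.2).
#' @param outcomes Outcome columns (default `c("stunted", "anaemic")`).
#' @param use_weights Passed to [weighted_crosstab()].
#' @return A list with `table` (one row per variable x outcome: statistic,
#'   df, p, retained flag), `retained` (per-outcome lists) and `union`
#'   (variables entering the joint model).
#' @export
screen_covariates <- function(records, codebook = default_codebook(),
                              variables = NULL, alpha = 0.2,
                              outcomes = c("stunted", "anaemic"),
                              use_weights = TRUE) {
  if (is.null(variables)) {
    variables <- intersect(names(codebook$variables), names(records))
  }
  stopifnot(length(variables) >= 1, alpha > 0, alpha < 1)
  rows <- list()
  for (v in variables) {
    for (oc in outcomes) {
      xt <- weighted_crosstab(records, v, oc, use_weights)
      tst <- chi2_test(xt$counts)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, outcome = oc, statistic = tst$statistic, df = tst$df,
        p_value = tst$p_value, retained = tst$p_value < alpha,
        n_dropped = xt$n_dropped, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  retained <- lapply(outcomes, function(oc)
    tab$variable[tab$outcome == oc & tab$retained])
  names(retained) <- outcomes
  union_vars <- variables[variables %in% unique(unlist(retained))]
  list(table = tab, retained = retained, union = union_vars)
}

#' Required sample size for a proportion
#'
#' The classical `n = z^2 p (1 - p) / d^2` formula for estimating a
#' proportion `p` with margin of error `d`.
#'
#' @param p Anticipated proportion, in `[0, 1]`.
#' @param z Normal quantile (default 1.96).
#' @param d Margin of error (> 0).
#' @return List with `n` (real) and `n_ceiling`.
#' @export
required_sample_size <- function(p, z = 1.96, d = 0.05) {
  stopifnot(p >= 0, p <= 1)
  if (d <= 0) stop("margin of error d must be positive")
  n <- z^2 * p * (1 - p) / d^2
  list(n = n, n_ceiling = ceiling(n))
}
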