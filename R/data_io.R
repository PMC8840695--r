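#' Child-level records
#'
#' Records are held as a plain data frame with one row per child. Mandatory
#' columns: `child_id`, `cluster_id`, `household_id`, `weight` (sampling
#' weight, positive). Optional numeric columns: `altitude_m`, `hb_gdl`
#' (haemoglobin g/dl), `haz` (height-for-age z score), `age_months`. Binary
#' outcome columns `anaemic` and `stunted` (0/1 or NA). Any further columns
#' named in the codebook are categorical covariates.
#'
#' @name child_records
NULL

CHILD_NUMERIC_COLS <- c("weight", "altitude_m", "hb_gdl", "haz", "age_months")
CHILD_OUTCOME_COLS <- c("anaemic", "stunted")

#' Validate a child-record table
#'
#' Enforces the record invariants: positive weights, haemoglobin (when
#' present) in (2, 25) g/dl, HAZ in (-7, 7), nonnegative altitude, and
#' covariate labels resolvable in the codebook.
#'
#' @param records Data frame of child records.
#' @param codebook A [codebook()].
#' @return The records, with covariate labels canonicalized to the codebook's
#'   spelling and coerced to factors (reference level first).
#' @export
validate_child_records <- function(records, codebook = default_codebook()) {
  for (col in c("cluster_id", "weight")) {
    if (!col %in% names(records)) {
      stop("mandatory column '", col, "' is missing")
    }
  }
  if (!"child_id" %in% names(records)) {
    records$child_id <- sprintf("ch%05d", seq_len(nrow(records)))
  }
  w <- records$weight
  if (anyNA(w) || any(w <= 0)) {
    stop("weight must be positive for every record (rows: ",
         paste(utils::head(which(is.na(w) | w <= 0), 5), collapse = ", "), ")")
  }
  chk_range <- function(x, lo, hi, nm) {
    bad <- !is.na(x) & (x <= lo | x >= hi)
    if (any(bad)) {
      stop(nm, " out of (", lo, ", ", hi, ") at rows: ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    }
  }
  if ("hb_gdl" %in% names(records)) chk_range(records$hb_gdl, 2, 25, "hb_gdl")
  if ("haz" %in% names(records)) chk_range(records$haz, -7, 7, "haz")
  if ("altitude_m" %in% names(records)) {
    bad <- !is.na(records$altitude_m) & records$altitude_m < 0
    if (any(bad)) stop("altitude_m must be nonnegative")
  }
  for (v in intersect(names(codebook$variables), names(records))) {
    records[[v]] <- resolve_labels(records[[v]], v, codebook)
  }
  for (v in intersect(CHILD_OUTCOME_COLS, names(records))) {
    x <- records[[v]]
    if (!all(is.na(x) | x %in% c(0, 1))) stop("'", v, "' must be 0/1 or NA")
    records[[v]] <- as.integer(x)
  }
  records
}

#' Load a child-record CSV
#'
#' Reads a UTF-8 CSV with a header row, maps blank cells and codebook missing
#' codes to `NA`, validates invariants, and rejects unknown category labels.
#'
#' @param path CSV path.
#' @param codebook A [codebook()].
#' @return A validated data frame of child records.
#' @export
load_children_table <- function(path, codebook = default_codebook()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                        fileEncoding = "UTF-8")
  for (col in intersect(CHILD_NUMERIC_COLS, names(df))) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(num <- as.numeric(df[[col]]))
      bad <- which(!is.na(df[[col]]) & is.na(num))
      if (length(bad)) {
        stop("unparseable numeric in column '", col, "' at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
      }
      df[[col]] <- num
    }
  }
  validate_child_records(df, codebook)
}

#' Write child records to CSV
#'
#' @param records Data frame of child records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_children_table <- function(records, path) {
  out <- records
  for (col in names(out)) if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Encode categorical covariates as a fixed-effect design matrix
#'
#' Builds an intercept plus one indicator column per non-reference level per
#' selected variable (treatment coding against the codebook reference).
#' Records missing any selected variable are dropped listwise and counted.
#'
#' @param records Validated child records.
#' @param codebook A [codebook()].
#' @param selected Character vector of covariate names to encode.
#' @return A list with `X` (numeric design matrix, first column intercept),
#'   `rows` (row indices of `records` retained), `dropped` (count removed by
#'   listwise deletion), and `terms` (data frame mapping columns to
#'   variable/level).
#' @export
encode_covariates <- function(records, codebook = default_codebook(),
                              selected = NULL) {
  if (is.null(selected)) {
    selected <- intersect(names(codebook$variables), names(records))
  }
  missing_vars <- setdiff(selected, names(codebook$variables))
  if (length(missing_vars)) {
    stop("not in codebook: ", paste(missing_vars, collapse = ", "))
  }
  missing_cols <- setdiff(selected, names(records))
  if (length(missing_cols)) {
    stop("not in records: ", paste(missing_cols, collapse = ", "))
  }
  if (length(selected) == 0) {
    return(list(X = matrix(1, nrow(records), 1,
                           dimnames = list(NULL, "(Intercept)")),
                rows = seq_len(nrow(records)), dropped = 0L,
                terms = data.frame(column = "(Intercept)", variable = "(Intercept)",
                                   level = "", stringsAsFactors = FALSE)))
  }
  fac <- records[selected]
  for (v in selected) fac[[v]] <- resolve_labels(fac[[v]], v, codebook)
  keep <- stats::complete.cases(fac)
  dropped <- sum(!keep)
  fac <- fac[keep, , drop = FALSE]
  if (nrow(fac) == 0) stop("no records remain after listwise deletion")
  for (v in selected) {
    obs <- unique(as.character(fac[[v]]))
    if (length(obs) < 2) {
      stop("variable '", v, "' has a single observed level ('", obs,
           "'); not identifiable")
    }
    fac[[v]] <- droplevels(fac[[v]])
  }
  X <- stats::model.matrix(~ ., data = fac)
  terms <- data.frame(column = colnames(X), variable = "(Intercept)",
                      level = "", stringsAsFactors = FALSE)
  assign_idx <- attr(X, "assign")
  for (k in seq_along(selected)) {
    sel <- assign_idx == k
    terms$variable[sel] <- selected[k]
    terms$level[sel] <- sub(paste0("^", selected[k]), "", colnames(X)[sel])
  }
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  list(X = X, rows = which(keep), dropped = dropped, terms = terms)
}

#' Write a JSON run manifest
#'
#' @param path Output path.
#' @param seed Seed used.
#' @param config An `analysis_config`.
#' @param extra Named list of further entries (e.g. dropped-row counts).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, config, extra = list()) {
  manifest <- c(list(
    package = "bivglmm",
    version = as.character(utils::packageVersion("bivglmm")),
    seed = seed,
    config = unclass(config)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
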