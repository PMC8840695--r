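#' Codebook for categorical covariates
#'
#' A codebook lists, for every categorical covariate, its ordered category
#' labels, the designated reference level, and its role (demographic or
#' socio-economic). All label matching elsewhere in the package is
#' case-insensitive after trimming, because survey exports vary in casing.
#'
#' @param variables Named list; each element is a list with components
#'   `levels` (character vector of category labels), `ref` (reference level,
#'   must be one of `levels`), `role` (`"demographic"` or
#'   `"socio-economic"`), and optionally `missing_codes` (labels to treat as
#'   missing, default `c("", "NA", "Missing")`).
#' @return An object of class `codebook`.
#' @export
codebook <- function(variables) {
  stopifnot(is.list(variables), length(variables) > 0, !is.null(names(variables)))
  for (v in names(variables)) {
    spec <- variables[[v]]
    if (is.null(spec$levels) || is.null(spec$ref)) {
      stop("codebook variable '", v, "' needs 'levels' and 'ref'")
    }
    if (anyDuplicated(tolower(trimws(spec$levels)))) {
      stop("codebook variable '", v, "' has duplicate levels")
    }
    if (!norm_label(spec$ref) %in% norm_label(spec$levels)) {
      stop("codebook variable '", v, "': reference level '", spec$ref,
           "' is not among its levels")
    }
    if (is.null(spec$role)) spec$role <- "demographic"
    if (is.null(spec$missing_codes)) spec$missing_codes <- c("", "NA", "Missing")
    variables[[v]] <- spec
  }
  structure(list(variables = variables), class = "codebook")
}

# canonical form used for case-insensitive matching
norm_label <- function(x) tolower(trimws(as.character(x)))

#' @export
print.codebook <- function(x, ...) {
  cat("Codebook with", length(x$variables), "variables:\n")
  for (v in names(x$variables)) {
    s <- x$variables[[v]]
    cat(sprintf("  %-14s [%s] levels: %s (ref: %s)\n", v, s$role,
                paste(s$levels, collapse = ", "), s$ref))
  }
  invisible(x)
}

#' Default codebook for the DHS-like child cohort
#'
#' Covers the covariates carried into the joint model (child age group,
#' fever, diarrhoea, birth weight, residence, household wealth, maternal
#' education) plus sex and cough, which appear only in the screening stage.
#' Reference levels follow the multivariable reporting convention of the
#' analysis this package implements: age "40-59 months", fever "Yes",
#' diarrhoea "Yes", birth weight "<2500 g", residence "Urban", wealth
#' "Richer", education "No education".
#'
#' @return A `codebook`.
#' @export
default_codebook <- function() {
  codebook(list(
    age_group = list(levels = c("40-59", "20-39", "6-19"), ref = "40-59",
                     role = "demographic"),
    sex = list(levels = c("Male", "Female"), ref = "Male",
               role = "demographic"),
    fever = list(levels = c("Yes", "No"), ref = "Yes", role = "demographic"),
    diarrhoea = list(levels = c("Yes", "No"), ref = "Yes",
                     role = "demographic"),
    cough = list(levels = c("Yes", "No"), ref = "Yes", role = "demographic"),
    birth_weight = list(levels = c("<2500 g", ">=2500 g"), ref = "<2500 g",
                        role = "demographic"),
    residence = list(levels = c("Urban", "Rural"), ref = "Urban",
                     role = "socio-economic"),
    wealth = list(levels = c("Richer", "Middle", "Poorer"), ref = "Richer",
                  role = "socio-economic"),
    education = list(levels = c("No education", "Primary", "Post primary"),
                     ref = "No education", role = "socio-economic")
  ))
}

#' Read or write a codebook as YAML
#'
#' @param path File path.
#' @return `read_codebook` returns a `codebook`; `write_codebook` returns
#'   `path` invisibly.
#' @export
read_codebook <- function(path) {
  codebook(yaml::read_yaml(path))
}

#' @rdname read_codebook
#' @param cb A `codebook`.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  yaml::write_yaml(cb$variables, path)
  invisible(path)
}

# resolve a vector of observed labels against codebook levels
# (case-insensitive, trimmed); unknown labels are an error, missing codes
# map to NA. Returns a factor with the reference level first.
resolve_labels <- function(x, var, cb) {
  spec <- cb$variables[[var]]
  if (is.null(spec)) stop("variable '", var, "' is not in the codebook")
  nx <- norm_label(x)
  nx[nx %in% norm_label(spec$missing_codes)] <- NA
  nx[is.na(x)] <- NA
  nlv <- norm_label(spec$levels)
  bad <- !is.na(nx) & !(nx %in% nlv)
  if (any(bad)) {
    stop("variable '", var, "': unknown category label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  canon <- spec$levels[match(nx, nlv)]
  ord <- c(spec$ref, setdiff(spec$levels, spec$ref))
  factor(canon, levels = ord)
}
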