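#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline: outcome cutoffs, the
#' screening and final significance levels, quadrature size, optimizer
#' tolerances, seed and weighting switch.
#'
#' @param anaemia_cutoff Haemoglobin cutoff in g/dl on the altitude-adjusted
#'   scale (default 11: children 6-59 months).
#' @param stunting_cutoff Height-for-age z-score cutoff in SD units
#'   (default -2).
#' @param screening_alpha Univariate retention level (default 0.2).
#' @param final_alpha Significance level for final reporting (default 0.05).
#' @param nodes Gauss-Hermite nodes per random-effect dimension (default 7).
#' @param optim_reltol Relative log-likelihood convergence tolerance.
#' @param grad_tol Gradient-norm threshold used to flag convergence.
#' @param seed Integer seed governing all randomness.
#' @param use_weights Use sampling weights in the screening crosstabs
#'   (default TRUE). Model fitting is unweighted by default; see the
#'   methods vignette.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(anaemia_cutoff = 11,
                            stunting_cutoff = -2,
                            screening_alpha = 0.2,
                            final_alpha = 0.05,
                            nodes = 7,
                            optim_reltol = 1e-9,
                            grad_tol = 1e-5,
                            seed = 1L,
                            use_weights = TRUE) {
  stopifnot(is.finite(anaemia_cutoff), is.finite(stunting_cutoff),
            screening_alpha > 0, screening_alpha < 1,
            final_alpha > 0, final_alpha < 1,
            nodes >= 1, optim_reltol > 0, grad_tol > 0)
  structure(list(
    anaemia_cutoff = anaemia_cutoff,
    stunting_cutoff = stunting_cutoff,
    screening_alpha = screening_alpha,
    final_alpha = final_alpha,
    nodes = as.integer(nodes),
    optim_reltol = optim_reltol,
    grad_tol = grad_tol,
    seed = as.integer(seed),
    use_weights = isTRUE(use_weights)
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  cat(sprintf("  anaemia cutoff: %g g/dl (altitude-adjusted)\n", x$anaemia_cutoff))
  cat(sprintf("  stunting cutoff: %g SD\n", x$stunting_cutoff))
  cat(sprintf("  screening alpha: %g; final alpha: %g\n",
              x$screening_alpha, x$final_alpha))
  cat(sprintf("  quadrature nodes/dim: %d; seed: %d; weights in crosstabs: %s\n",
              x$nodes, x$seed, x$use_weights))
  invisible(x)
}

#' @rdname analysis_config
#' @param path File path for YAML serialization.
#' @export
read_analysis_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' @rdname analysis_config
#' @param config An `analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
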