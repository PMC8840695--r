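#' Format a p-value for reporting
#'
#' Three decimals, with values below 0.001 shown as `"<0.001"`.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_pval <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' Odds-ratio / confidence-interval table for a joint fit
#'
#' One row per coefficient and per variance/covariance component:
#' estimate (log-odds), SE, `OR = exp(estimate)`, Wald CI
#' `exp(estimate +/- z * SE)` and two-sided Wald p. The exponential of the
#' variance/covariance components is reported in the OR column as a display
#' convention only (flagged in the `note` column); it is not an
#' interpretable odds ratio.
#'
#' @param fit A `joint_glmm_fit`.
#' @param alpha CI level (default 0.05).
#' @param z Normal quantile; defaults to 1.96 when `alpha = 0.05`
#'   (reporting convention), otherwise `qnorm(1 - alpha/2)`.
#' @return Data frame of class `effect_table`.
#' @export
or_ci_table <- function(fit, alpha = 0.05, z = NULL) {
  stopifnot(inherits(fit, "joint_glmm_fit"))
  if (is.null(z)) z <- if (identical(alpha, 0.05)) 1.96 else stats::qnorm(1 - alpha / 2)
  p <- length(fit$theta1)
  est <- c(fit$theta1, fit$theta2, fit$sigma)
  se <- fit$se
  outcome <- c(rep(fit$outcomes[1], p), rep(fit$outcomes[2], p),
               rep("random effects", 3))
  term_var <- c(fit$terms$variable, fit$terms$variable,
                paste0("Variance (", fit$outcomes[1], ")"),
                "Covariance", paste0("Variance (", fit$outcomes[2], ")"))
  term_lvl <- c(fit$terms$level, fit$terms$level, "", "", "")
  note <- c(rep("", 2 * p), rep("exp(component): display convention, not an odds ratio", 3))
  wald_p <- ifelse(is.na(se) | se == 0, NA_real_,
                   2 * stats::pnorm(-abs(est / se)))
  out <- data.frame(
    outcome = outcome, variable = term_var, level = term_lvl,
    estimate = unname(est), se = unname(se),
    or = exp(unname(est)),
    ci_lower = exp(unname(est) - z * unname(se)),
    ci_upper = exp(unname(est) + z * unname(se)),
    p_value = unname(wald_p),
    p_display = format_pval(unname(wald_p)),
    note = note, stringsAsFactors = FALSE)
  if (!fit$se_available) {
    out$ci_lower <- out$ci_upper <- out$p_value <- NA_real_
    out$p_display <- NA_character_
    out$note <- paste(out$note, "(SEs unavailable)")
  }
  class(out) <- c("effect_table", "data.frame")
  out
}

new_variance_test <- function(component, method, statistic, null_dist, p) {
  structure(list(component = component, method = method,
                 statistic = statistic, null_distribution = null_dist,
                 p_value = p), class = "variance_test")
}

#' @export
print.variance_test <- function(x, ...) {
  cat(sprintf("Test of %s = 0 (%s): statistic %.4f, %s, p %s\n",
              x$component, x$method, x$statistic, x$null_distribution,
              format_pval(x$p_value)))
  invisible(x)
}

#' Test the cross-outcome covariance against zero
#'
#' Null `sigma12 = 0` with both variances in the interior of the parameter
#' space, so the LRT statistic `2 (ll_joint - ll_independent)` is referred
#' to chi-square with 1 df. Alternatives: Wald `(sigma12_hat / SE)^2`, or
#' the score test evaluated at the independence fit.
#'
#' @param fit_joint A `joint_glmm_fit` (unconstrained).
#' @param fit_independent An `independent_glmm_fits` (or any object with a
#'   `loglik` field for the constrained model).
#' @param method `"lrt"` (default), `"wald"` or `"score"`.
#' @param design,config Required for `method = "score"`.
#' @return A `variance_test`.
#' @export
test_covariance_zero <- function(fit_joint, fit_independent,
                                 method = c("lrt", "wald", "score"),
                                 design = NULL, config = analysis_config()) {
  method <- match.arg(method)
  if (method == "lrt") {
    T <- 2 * (fit_joint$loglik - fit_independent$loglik)
    if (T < -1e-3) {
      stop("negative LRT statistic (", format(T), "): optimizer failure; ",
           "the independent fit exceeds the joint fit")
    }
    T <- max(T, 0)
    p <- stats::pchisq(T, df = 1, lower.tail = FALSE)
    return(new_variance_test("sigma12", "lrt", T, "chi-square(1)", p))
  }
  if (method == "wald") {
    s12 <- fit_joint$sigma["sigma12"]
    se <- fit_joint$se["sigma12"]
    if (is.na(se) || se == 0) stop("Wald test unavailable: no SE for sigma12")
    T <- unname((s12 / se)^2)
    p <- stats::pchisq(T, df = 1, lower.tail = FALSE)
    return(new_variance_test("sigma12", "wald", T, "chi-square(1)", p))
  }
  # score test at the independence fit
  if (is.null(design)) stop("score test needs the stacked design")
  f1 <- fit_independent$fits[[1]]; f2 <- fit_independent$fits[[2]]
  par0 <- c(f1$theta, f2$theta,
            0.5 * log(max(f1$sigma2, 1e-6)), 0, 0.5 * log(max(f2$sigma2, 1e-6)))
  gh <- gh_rule(config$nodes)
  nll <- function(par) {
    agq_joint_nll_cpp(par, design$X1, design$y1, as.integer(design$cl1),
                      design$w1, design$X2, design$y2, as.integer(design$cl2),
                      design$w2, design$n_clusters, gh$x, gh$logw)
  }
  U <- -num_grad(nll, par0)          # score of the log-likelihood
  I <- stats::optimHess(par0, nll)   # observed information
  T <- drop(t(U) %*% solve(I, U))
  T <- max(T, 0)
  p <- stats::pchisq(T, df = 1, lower.tail = FALSE)
  new_variance_test("sigma12", "score", T, "chi-square(1)", p)
}

#' Boundary test of a random-intercept variance
#'
#' A variance cannot be negative, so zero lies on the boundary of the
#' parameter space and the naive chi-square(1) reference is conservative.
#' The LRT statistic `2 (ll_full - ll_reduced)` is referred to the 50:50
#' mixture of a point mass at zero and chi-square(1):
#' `p = 0.5 * P(chi2_1 >= T)` for `T > 0`, and `p = 1` at `T = 0`.
#'
#' @param fit_full Fit including the random intercept (e.g. a
#'   `uni_glmm_fit`), or any object with `loglik`.
#' @param fit_reduced Fit with the variance fixed at zero (e.g. a
#'   `fixed_logit_fit`).
#' @param component Label for the tested component.
#' @return A `variance_test`.
#' @export
test_variance_boundary <- function(fit_full, fit_reduced,
                                   component = "sigma2") {
  ll_full <- if (is.numeric(fit_full)) fit_full else fit_full$loglik
  ll_red <- if (is.numeric(fit_reduced)) fit_reduced else fit_reduced$loglik
  T <- 2 * (ll_full - ll_red)
  if (T < -1e-3) {
    stop("negative LRT statistic (", format(T), "): optimizer failure")
  }
  T <- max(T, 0)
  p <- if (T <= 0) 1 else 0.5 * stats::pchisq(T, df = 1, lower.tail = FALSE)
  new_variance_test(component, "lrt (50:50 mixture)", T,
                    "0.5*chi2(0) + 0.5*chi2(1)", p)
}

# marginal fitted probability E[expit(eta + u)], u ~ N(0, s2), plain GH
marginal_prob <- function(eta, s2, nodes = 31) {
  if (s2 <= 0) return(stats::plogis(eta))
  gh <- gh_rule(nodes)
  w <- exp(gh$logw) / sqrt(pi)
  sapply(eta, function(e) sum(w * stats::plogis(e + sqrt(2 * s2) * gh$x)))
}

#' Grouped Pearson goodness-of-fit statistic
#'
#' Records are grouped by identical covariate pattern (per outcome); within
#' group `i` of size `n_i`, the observed proportions `y_ij` over the two
#' response categories `j` are compared with the model's marginal fitted
#' probabilities: `chi2 = sum_i n_i sum_j (y_ij - pi_ij)^2 / pi_ij`. The
#' statistic is summed over both outcomes; degrees of freedom are the total
#' number of patterns minus the number of free model parameters, and the
#' statistic/df ratio is the overdispersion diagnostic.
#'
#' @param fit A `joint_glmm_fit`.
#' @param design The `stacked_design` the model was fitted on.
#' @param ratio_bound Overdispersion verdict bound (default 1.2).
#' @return An object of class `gof_result` with `statistic`, `df`, `ratio`,
#'   `verdict`, `n_patterns`.
#' @export
pearson_gof <- function(fit, design, ratio_bound = 1.2) {
  one_outcome <- function(X, y, theta, s2) {
    eta <- drop(X %*% theta)
    pat <- apply(X, 1, paste, collapse = "\r")
    stat <- 0
    npat <- 0L
    for (g in unique(pat)) {
      idx <- which(pat == g)
      n_i <- length(idx)
      pi1 <- marginal_prob(eta[idx[1]], s2)
      obs1 <- mean(y[idx])
      stat <- stat + n_i * ((obs1 - pi1)^2 / pi1 +
                            ((1 - obs1) - (1 - pi1))^2 / (1 - pi1))
      npat <- npat + 1L
    }
    list(stat = stat, npat = npat)
  }
  r1 <- one_outcome(design$X1, design$y1, fit$theta1, unname(fit$sigma["sigma11"]))
  r2 <- one_outcome(design$X2, design$y2, fit$theta2, unname(fit$sigma["sigma22"]))
  statistic <- unname(r1$stat + r2$stat)
  n_patterns <- r1$npat + r2$npat
  df <- n_patterns - sum(fit$free)
  ratio <- if (df > 0) statistic / df else NA_real_
  verdict <- if (is.na(ratio)) "df not positive: ratio unavailable"
    else if (ratio <= ratio_bound) "none detected" else "possible overdispersion"
  structure(list(statistic = statistic, df = df, ratio = ratio,
                 verdict = verdict, n_patterns = n_patterns,
                 ratio_bound = ratio_bound), class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Grouped Pearson goodness-of-fit: chi2 = %.3f on %d df (%d patterns)\n",
              x$statistic, x$df, x$n_patterns))
  cat(sprintf("  statistic/df = %s; overdispersion: %s\n",
              ifelse(is.na(x$ratio), "NA", sprintf("%.3f", x$ratio)), x$verdict))
  invisible(x)
}
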