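#' Random-effect covariance matrix
#'
#' Constructs the 2x2 covariance of the paired cluster-level random
#' intercepts (stunting, anaemia), checking positive semidefiniteness.
#'
#' @param sigma11 Variance of the stunting random intercept (>= 0).
#' @param sigma22 Variance of the anaemia random intercept (>= 0).
#' @param sigma12 Cross-outcome covariance; must satisfy
#'   `sigma12^2 <= sigma11 * sigma22`.
#' @return A symmetric 2x2 matrix with dimnames `c("stunted", "anaemic")`.
#' @export
make_sigma <- function(sigma11, sigma22, sigma12 = 0) {
  stopifnot(is.finite(sigma11), is.finite(sigma22), is.finite(sigma12))
  if (sigma11 < 0 || sigma22 < 0) stop("variances must be nonnegative")
  if (sigma12^2 > sigma11 * sigma22 + 1e-12) {
    stop("sigma12^2 exceeds sigma11*sigma22: covariance not positive semidefinite")
  }
  matrix(c(sigma11, sigma12, sigma12, sigma22), 2, 2,
         dimnames = list(c("stunted", "anaemic"), c("stunted", "anaemic")))
}

# lower-triangular factor of a 2x2 PSD matrix (handles singular cases)
chol2_psd <- function(Sigma) {
  s11 <- Sigma[1, 1]; s22 <- Sigma[2, 2]; s12 <- Sigma[1, 2]
  a <- sqrt(s11)
  b <- if (a > 0) s12 / a else 0
  c2 <- max(s22 - b^2, 0)
  matrix(c(a, b, 0, sqrt(c2)), 2, 2)
}

#' Ground-truth parameter set for simulation
#'
#' @param theta1,theta2 Named fixed-effect vectors (log-odds scale) for
#'   stunting and anaemia; names must match the encoded design columns,
#'   including `"(Intercept)"`.
#' @param Sigma 2x2 random-effect covariance, see [make_sigma()].
#' @param n_clusters Number of clusters (enumeration areas).
#' @param mean_children Mean of the (>=1-truncated) Poisson number of
#'   children per cluster.
#' @param marginals Named list of per-variable category probabilities
#'   (aligned with the codebook level order); must each sum to 1.
#' @param seed Integer seed.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(theta1, theta2, Sigma, n_clusters = 400,
                             mean_children = 8,
                             marginals = default_marginals(), seed = 1L) {
  stopifnot(!is.null(names(theta1)), !is.null(names(theta2)),
            "(Intercept)" %in% names(theta1), "(Intercept)" %in% names(theta2),
            identical(names(theta1), names(theta2)),
            n_clusters >= 1, mean_children > 0)
  for (v in names(marginals)) {
    if (abs(sum(marginals[[v]]) - 1) > 1e-8) {
      stop("marginals for '", v, "' do not sum to 1")
    }
  }
  make_sigma(Sigma[1, 1], Sigma[2, 2], Sigma[1, 2])  # validates PSD
  structure(list(theta1 = theta1, theta2 = theta2, Sigma = Sigma,
                 n_clusters = as.integer(n_clusters),
                 mean_children = mean_children,
                 marginals = marginals, seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Default covariate marginals
#'
#' Category frequencies approximating the published univariate tables of the
#' 2014 Lesotho DHS child sample; covariates are drawn independently across
#' variables (no joint distribution is published).
#'
#' @return Named list of probability vectors, ordered as the codebook levels.
#' @export
default_marginals <- function() {
  list(
    age_group = c("40-59" = 0.28, "20-39" = 0.32, "6-19" = 0.40),
    sex = c(Male = 0.46, Female = 0.54),
    fever = c(Yes = 0.17, No = 0.83),
    diarrhoea = c(Yes = 0.13, No = 0.87),
    cough = c(Yes = 0.30, No = 0.70),
    birth_weight = c("<2500 g" = 0.09, ">=2500 g" = 0.91),
    residence = c(Urban = 0.28, Rural = 0.72),
    wealth = c(Richer = 0.365, Middle = 0.21, Poorer = 0.425),
    education = c("No education" = 0.012, Primary = 0.46, "Post primary" = 0.528)
  )
}

# Fixed-effect point estimates reported for the joint model (log-odds).
# The age "<20 months" stunting coefficient uses the OR-implied sign
# (printed OR 0.436 = exp(-0.829)).
default_theta_effects <- function() {
  nms <- c("age_group20-39", "age_group6-19", "feverNo", "diarrhoeaNo",
           "birth_weight>=2500 g", "residenceRural", "wealthMiddle",
           "wealthPoorer", "educationPrimary", "educationPost primary")
  list(
    stunted = stats::setNames(
      c(0.226, -0.829, 0.153, -0.227, -1.248, -0.653, 1.065, 1.253,
        -1.473, -1.841), nms),
    anaemic = stats::setNames(
      c(0.531, 0.096, -0.712, -0.496, 0.038, 0.102, 0.224, 0.282,
        -0.772, -0.519), nms)
  )
}

# expected linear-predictor contribution of the covariates under independent
# marginals (used to calibrate intercepts to target prevalences)
mean_contribution <- function(theta_effects, marginals, codebook) {
  total <- 0
  for (v in names(codebook$variables)) {
    lv <- codebook$variables[[v]]$levels
    pr <- marginals[[v]]
    if (is.null(pr)) next
    for (l in setdiff(lv, codebook$variables[[v]]$ref)) {
      nm <- paste0(v, l)
      if (nm %in% names(theta_effects)) total <- total + pr[[l]] * theta_effects[[nm]]
    }
  }
  total
}

#' Default simulation truth
#'
#' Ground truth assembled from the published joint-model point estimates:
#' fixed effects from the reported coefficient table (with the one
#' OR-implied sign correction), random-effect variances
#' `sigma11 = 0.104`, `sigma22 = 0.314`, and the cross covariance capped at
#' the positive-semidefinite boundary `sqrt(sigma11*sigma22) ~= 0.181`
#' (the printed value 1.000 is not PSD-compatible with the printed
#' variances; see the methods vignette). Intercepts are calibrated so the
#' mean-covariate linear predictor hits the reported prevalences (43%
#' stunting, 51% anaemia).
#'
#' @param n_clusters,mean_children,seed See [simulation_truth()].
#' @param Sigma Optionally override the covariance matrix.
#' @param prevalence Length-2 target prevalences `c(stunted, anaemic)` used
#'   to calibrate intercepts.
#' @return A `simulation_truth`.
#' @export
default_truth <- function(n_clusters = 400, mean_children = 8, seed = 1L,
                          Sigma = NULL,
                          prevalence = c(stunted = 0.43, anaemic = 0.51)) {
  cb <- default_codebook()
  marg <- default_marginals()
  eff <- default_theta_effects()
  if (is.null(Sigma)) {
    s11 <- 0.104; s22 <- 0.314
    Sigma <- make_sigma(s11, s22, sqrt(s11 * s22))
  }
  int1 <- stats::qlogis(prevalence[[1]]) - mean_contribution(eff$stunted, marg, cb)
  int2 <- stats::qlogis(prevalence[[2]]) - mean_contribution(eff$anaemic, marg, cb)
  theta1 <- c("(Intercept)" = unname(int1), eff$stunted)
  theta2 <- c("(Intercept)" = unname(int2), eff$anaemic)
  simulation_truth(theta1, theta2, Sigma, n_clusters, mean_children,
                   marg, seed)
}

#' Draw paired cluster random effects
#'
#' One pair `(u1, u2)` per cluster, i.i.d. bivariate normal with mean zero
#' and the given covariance (singular covariances allowed).
#'
#' @param Sigma 2x2 positive semidefinite covariance.
#' @param n_clusters Number of clusters.
#' @param seed Integer seed.
#' @return `n_clusters` x 2 matrix.
#' @export
draw_cluster_effects <- function(Sigma, n_clusters, seed = 1L) {
  Sigma <- make_sigma(Sigma[1, 1], Sigma[2, 2], Sigma[1, 2])
  L <- chol2_psd(Sigma)
  set.seed(seed)
  Z <- matrix(stats::rnorm(2 * n_clusters), n_clusters, 2)
  U <- Z %*% t(L)
  colnames(U) <- c("u1", "u2")
  U
}

# variables whose effects appear in a truth object
truth_variables <- function(truth, codebook) {
  nms <- setdiff(names(truth$theta1), "(Intercept)")
  vars <- character(0)
  for (v in names(codebook$variables)) {
    lv <- setdiff(codebook$variables[[v]]$levels, codebook$variables[[v]]$ref)
    if (all(paste0(v, lv) %in% nms)) vars <- c(vars, v)
  }
  covered <- unlist(lapply(vars, function(v)
    paste0(v, setdiff(codebook$variables[[v]]$levels, codebook$variables[[v]]$ref))))
  if (!setequal(covered, nms)) {
    stop("theta names do not match the encoded design implied by the codebook: ",
         paste(setdiff(nms, covered), collapse = ", "))
  }
  vars
}

#' Simulate a DHS-like cohort from known ground truth
#'
#' Cluster sizes are Poisson(`mean_children`) truncated at 1; covariates are
#' drawn independently from the truth's marginals; cluster random-effect
#' pairs come from [draw_cluster_effects()]; outcomes are Bernoulli with
#' logit-linear probabilities `expit(x'theta_k + u_ck)`; sampling weights
#' are lognormal with mean 1. A single seed governs all draws through fixed
#' per-stage offsets (sizes/covariates: seed+1, random effects: seed+2,
#' outcomes: seed+3, weights: seed+4), so each stage is independently
#' reproducible.
#'
#' @param truth A [simulation_truth()].
#' @param codebook A [codebook()] the truth conforms to.
#' @param seed Integer seed (defaults to `truth$seed`).
#' @return Validated child records with `stunted` and `anaemic` outcome
#'   columns; the truth's cluster effects are attached as attribute
#'   `cluster_effects`.
#' @export
simulate_cohort <- function(truth, codebook = default_codebook(),
                            seed = truth$seed) {
  vars <- truth_variables(truth, codebook)
  C <- truth$n_clusters

  set.seed(seed + 1L)
  sz <- stats::rpois(C, truth$mean_children)
  sz[sz < 1] <- 1L
  N <- sum(sz)
  cl <- rep(seq_len(C), sz)

  cov_df <- data.frame(row.names = seq_len(N))
  for (v in names(truth$marginals)) {
    lv <- codebook$variables[[v]]$levels
    pr <- truth$marginals[[v]]
    if (!setequal(names(pr), lv)) {
      stop("marginals for '", v, "' do not match codebook levels")
    }
    draws <- sample(lv, N, replace = TRUE, prob = pr[lv])
    ref <- codebook$variables[[v]]$ref
    cov_df[[v]] <- factor(draws, levels = c(ref, setdiff(lv, ref)))
  }
  age_months <- rep(NA_integer_, N)
  if ("age_group" %in% names(cov_df)) {
    rng <- list("6-19" = 6:19, "20-39" = 20:39, "40-59" = 40:59)
    for (g in names(rng)) {
      idx <- which(as.character(cov_df$age_group) == g)
      if (length(idx)) age_months[idx] <- sample(rng[[g]], length(idx), replace = TRUE)
    }
  }

  X <- if (length(vars) == 0) {
    matrix(1, N, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = cov_df[vars])
  }
  attr(X, "assign") <- NULL
  if (!setequal(colnames(X), names(truth$theta1))) {
    stop("theta length/names mismatch with encoded design")
  }
  th1 <- truth$theta1[colnames(X)]
  th2 <- truth$theta2[colnames(X)]

  U <- draw_cluster_effects(truth$Sigma, C, seed + 2L)

  set.seed(seed + 3L)
  p1 <- stats::plogis(drop(X %*% th1) + U[cl, 1])
  p2 <- stats::plogis(drop(X %*% th2) + U[cl, 2])
  # inverse-CDF Bernoulli draws: one uniform per child per outcome, so each
  # outcome's stream is invariant to the other's parameters
  stunted <- as.integer(stats::runif(N) < p1)
  anaemic <- as.integer(stats::runif(N) < p2)

  set.seed(seed + 4L)
  sdlog <- 0.35
  weight <- stats::rlnorm(N, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  within_idx <- sequence(sz)
  rec <- data.frame(
    child_id = sprintf("ch%06d", seq_len(N)),
    cluster_id = sprintf("EA%04d", cl),
    household_id = sprintf("EA%04d-h%03d", cl, (within_idx + 1L) %/% 2L),
    weight = weight,
    age_months = age_months,
    stringsAsFactors = FALSE
  )
  rec <- cbind(rec, cov_df)
  rec$stunted <- stunted
  rec$anaemic <- anaemic
  rec <- validate_child_records(rec, codebook)
  attr(rec, "cluster_effects") <- U
  rec
}

#' Read or write a simulation truth as YAML
#'
#' The YAML schema mirrors [simulation_truth()]: named `theta1`/`theta2`
#' maps (log-odds, including `(Intercept)`), a `sigma` block with
#' `sigma11`/`sigma22`/`sigma12`, `n_clusters`, `mean_children`, `seed`,
#' and a `marginals` map of per-variable category probabilities. An example
#' file with the default parameter set ships as
#' `system.file("extdata", "default_truth.yaml", package = "bivglmm")`.
#'
#' @param path File path.
#' @return `read_simulation_truth` returns a `simulation_truth`.
#' @export
read_simulation_truth <- function(path) {
  y <- yaml::read_yaml(path)
  simulation_truth(
    theta1 = unlist(y$theta1), theta2 = unlist(y$theta2),
    Sigma = make_sigma(y$sigma$sigma11, y$sigma$sigma22, y$sigma$sigma12),
    n_clusters = y$n_clusters, mean_children = y$mean_children,
    marginals = lapply(y$marginals, unlist),
    seed = if (is.null(y$seed)) 1L else y$seed)
}

#' @rdname read_simulation_truth
#' @param truth A `simulation_truth`.
#' @export
write_simulation_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  yaml::write_yaml(list(
    theta1 = as.list(truth$theta1), theta2 = as.list(truth$theta2),
    sigma = list(sigma11 = truth$Sigma[1, 1], sigma22 = truth$Sigma[2, 2],
                 sigma12 = truth$Sigma[1, 2]),
    n_clusters = truth$n_clusters, mean_children = truth$mean_children,
    seed = truth$seed,
    marginals = lapply(truth$marginals, as.list)), path, precision = 12)
  invisible(path)
}

# inverse-CDF draw from a truncated normal
rtruncnorm_ <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Backfill biomarkers consistent with simulated binary outcomes
#'
#' Fills `hb_gdl`, `haz` and `altitude_m` so that re-deriving the outcomes
#' (altitude adjustment, then threshold classification) reproduces the
#' simulated binary flags exactly. Adjusted-scale haemoglobin is drawn from
#' a truncated normal strictly below the anaemia cutoff for anaemic
#' children and above it otherwise, then un-adjusted by adding back the
#' altitude term for a uniformly drawn altitude; HAZ is drawn around the
#' stunting cutoff in the same way.
#'
#' @param records Records carrying `stunted`/`anaemic` flags.
#' @param config An [analysis_config()] (supplies the cutoffs).
#' @param seed Integer seed.
#' @param altitude_range Altitude range in metres (default 1400-3400,
#'   spanning the Lesotho highlands).
#' @return Records with biomarker columns filled.
#' @export
backfill_biomarkers <- function(records, config = analysis_config(),
                                seed = 1L, altitude_range = c(1400, 3400)) {
  n <- nrow(records)
  cut_hb <- config$anaemia_cutoff
  cut_haz <- config$stunting_cutoff
  set.seed(seed + 5L)
  altitude <- stats::runif(n, altitude_range[1], altitude_range[2])

  an <- records$anaemic
  hb_adj <- numeric(n)
  i1 <- which(!is.na(an) & an == 1)
  i0 <- which(!is.na(an) & an == 0)
  ina <- which(is.na(an))
  hb_adj[i1] <- rtruncnorm_(length(i1), 9.8, 1.5, 2.6, cut_hb - 1e-6)
  hb_adj[i0] <- rtruncnorm_(length(i0), 12.6, 1.2, cut_hb + 1e-6, 18.5)
  hb_adj[ina] <- rtruncnorm_(length(ina), 12.0, 1.8, 2.6, 18.5)
  A <- altitude * 3.2808399 / 1000
  adj <- pmax(0, -0.032 * A + 0.022 * A^2)
  records$altitude_m <- altitude
  records$hb_gdl <- hb_adj + adj

  st <- records$stunted
  haz <- numeric(n)
  j1 <- which(!is.na(st) & st == 1)
  j0 <- which(!is.na(st) & st == 0)
  jna <- which(is.na(st))
  haz[j1] <- rtruncnorm_(length(j1), -2.9, 0.7, -6.9, cut_haz - 1e-6)
  haz[j0] <- rtruncnorm_(length(j0), -0.7, 1.1, cut_haz + 1e-6, 6.9)
  haz[jna] <- rtruncnorm_(length(jna), -1.2, 1.3, -6.9, 6.9)
  records$haz <- haz
  records
}
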