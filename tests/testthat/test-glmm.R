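test_that("stacked design has one row per observed child-outcome pair", {
  rec <- validate_child_records(data.frame(
    child_id = c("c1", "c2"), cluster_id = "A", household_id = "h",
    weight = 1, stunted = c(1L, 0L), anaemic = c(0L, 1L),
    stringsAsFactors = FALSE))
  d <- build_stacked_design(rec)
  expect_identical(length(d$y1) + length(d$y2), 4L)
  # intercept-only: single column of ones per outcome
  expect_identical(ncol(d$X1), 1L)
  expect_true(all(d$X1 == 1) && all(d$X2 == 1))

  rec$anaemic[1] <- NA
  d2 <- build_stacked_design(rec)
  expect_identical(length(d2$y1), 2L)
  expect_identical(length(d2$y2), 1L)

  rec$stunted <- NA
  rec$anaemic <- NA
  expect_error(build_stacked_design(validate_child_records(rec)),
               "zero usable rows")
})

test_that("the likelihood collapses to independent Bernoullis as Sigma -> 0", {
  rec <- validate_child_records(data.frame(
    child_id = "c", cluster_id = "A", household_id = "h", weight = 1,
    stunted = 1L, anaemic = 0L, stringsAsFactors = FALSE))
  d <- build_stacked_design(rec)
  expect_equal(marginal_loglikelihood(d, 0, 0, make_sigma(0, 0, 0)),
               2 * log(0.5), tolerance = 1e-12)
})

test_that("AGQ matches a dense grid-integration oracle on small instances", {
  d <- tiny_design()
  set.seed(53)
  for (rep in 1:3) {
    th1 <- rnorm(2, 0, 0.7)
    th2 <- rnorm(2, 0, 0.7)
    Sig <- matrix(c(0.5, 0.2, 0.2, 0.5), 2)
    ll_agq <- marginal_loglikelihood(d, th1, th2, Sig, nodes = 25)
    ll_grid <- grid_oracle_ll(d, th1, th2, Sig)
    expect_lt(abs(ll_agq - ll_grid), 1e-6)
  }
  # an anisotropic, correlated covariance
  Sig2 <- matrix(c(0.8, -0.3, -0.3, 0.3), 2)
  expect_lt(abs(marginal_loglikelihood(d, c(0.2, -0.4), c(-0.1, 0.6), Sig2,
                                       nodes = 25) -
                grid_oracle_ll(d, c(0.2, -0.4), c(-0.1, 0.6), Sig2)), 1e-6)
})

test_that("laplace equals one-node AGQ and quadrature converges in node count", {
  d <- tiny_design()
  Sig <- matrix(c(0.5, 0.2, 0.2, 0.5), 2)
  expect_identical(
    marginal_loglikelihood(d, c(0.3, -0.5), c(-0.2, 0.4), Sig, method = "laplace"),
    marginal_loglikelihood(d, c(0.3, -0.5), c(-0.2, 0.4), Sig, nodes = 1))

  cohort <- small_cohort(n_clusters = 50, mean_children = 6, seed = 59)
  des <- build_stacked_design(cohort, c("fever", "wealth"))
  th1 <- rep(0.2, des$p)
  th2 <- rep(-0.1, des$p)
  Sig <- make_sigma(0.6, 0.6, 0.3)
  ll7 <- marginal_loglikelihood(des, th1, th2, Sig, nodes = 7)
  ll15 <- marginal_loglikelihood(des, th1, th2, Sig, nodes = 15)
  expect_lt(abs(ll7 - ll15), 1e-4)
})

test_that("degenerate covariances collapse to the matching lower-dimensional integral", {
  d <- tiny_design()
  th1 <- c(0.3, -0.5)
  th2 <- c(-0.2, 0.4)
  # one zero variance: outcome 1 contributes plain Bernoulli terms
  ll <- marginal_loglikelihood(d, th1, th2, make_sigma(0, 0.5, 0), nodes = 15)
  eta1 <- drop(d$X1 %*% th1)
  bern1 <- sum(eta1 * d$y1 - log(1 + exp(eta1)))
  uni <- marginal_loglikelihood(d, th1, th2, make_sigma(1e-14, 0.5, 0), nodes = 15)
  expect_equal(ll, uni, tolerance = 1e-6)
  expect_lt(ll, bern1)  # outcome-2 block adds negative terms
  # perfectly correlated covariance: compare against a direct 1-D trapezoid
  # oracle along u = t * (sqrt(s11), sqrt(s22)), t ~ N(0, 1)
  Sig_sing <- make_sigma(0.4, 0.4, 0.4)
  ll_line <- marginal_loglikelihood(d, th1, th2, Sig_sing, nodes = 25)
  tgrid <- seq(-8, 8, length.out = 20001)
  ht <- tgrid[2] - tgrid[1]
  v <- sqrt(c(0.4, 0.4))
  ll_oracle <- 0
  for (c in seq_len(d$n_clusters) - 1L) {
    r1 <- which(d$cl1 == c)
    r2 <- which(d$cl2 == c)
    G <- dnorm(tgrid, log = TRUE)
    for (k in r1) G <- G + bern_ll_vec(drop(d$X1[k, ] %*% th1) + tgrid * v[1], d$y1[k])
    for (k in r2) G <- G + bern_ll_vec(drop(d$X2[k, ] %*% th2) + tgrid * v[2], d$y2[k])
    ll_oracle <- ll_oracle + log(sum(exp(G)) * ht)
  }
  expect_lt(abs(ll_line - ll_oracle), 1e-6)
})

test_that("constrained joint likelihood factorizes into the univariate fits", {
  cohort <- small_cohort(n_clusters = 40, mean_children = 5, seed = 61)
  des <- build_stacked_design(cohort, "fever")
  cfg <- analysis_config(nodes = 7)
  indep <- fit_independent_models(des, cfg)
  f1 <- indep$fits[[1]]
  f2 <- indep$fits[[2]]
  # identity: evaluating the joint likelihood at the combined univariate
  # estimates with a diagonal covariance reproduces the summed likelihoods
  ll_joint_at <- marginal_loglikelihood(
    des, f1$theta, f2$theta, make_sigma(f1$sigma2, f2$sigma2, 0), nodes = 7)
  expect_equal(ll_joint_at, indep$loglik, tolerance = 1e-6)
  # optimizing the sigma12 = 0-constrained joint model reaches the same optimum
  constrained <- fit_joint_model(des, cfg, fixed = c(l21 = 0))
  expect_equal(constrained$loglik, indep$loglik, tolerance = 1e-5)
  # nesting: the unconstrained fit can only do better
  joint <- fit_joint_model(des, cfg)
  expect_gte(joint$loglik, constrained$loglik - 1e-8)
  expect_gte(joint$loglik, indep$loglik - 1e-8)
})

test_that("under a sigma12 = 0 truth, joint and independent estimates agree", {
  truth <- default_truth(n_clusters = 80, mean_children = 6, seed = 67,
                         Sigma = make_sigma(0.5, 0.5, 0))
  cohort <- simulate_cohort(truth)
  des <- build_stacked_design(cohort, c("fever", "residence"))
  cfg <- analysis_config(nodes = 7)
  joint <- fit_joint_model(des, cfg)
  indep <- fit_independent_models(des, cfg)
  expect_equal(unname(joint$theta1), unname(indep$fits[[1]]$theta),
               tolerance = 0.05)
  expect_equal(unname(joint$theta2), unname(indep$fits[[2]]$theta),
               tolerance = 0.05)
})

test_that("with no cluster variance the joint fit matches plain logistic regression", {
  # truth restricted to the modelled covariates so the fitted conditional
  # effects are directly comparable (logistic effects do not collapse over
  # omitted covariates)
  marg <- default_marginals()[c("fever", "wealth")]
  truth <- simulation_truth(
    theta1 = c("(Intercept)" = -0.4, feverNo = 0.3, wealthMiddle = 0.8,
               wealthPoorer = 1.1),
    theta2 = c("(Intercept)" = 0.2, feverNo = -0.7, wealthMiddle = 0.2,
               wealthPoorer = 0.3),
    Sigma = make_sigma(0, 0, 0), n_clusters = 250, mean_children = 6,
    marginals = marg, seed = 71)
  cohort <- simulate_cohort(truth)
  des <- build_stacked_design(cohort, c("fever", "wealth"))
  fit <- fit_joint_model(des, analysis_config(nodes = 5))
  g1 <- glm.fit(des$X1, des$y1, family = binomial())$coefficients
  g2 <- glm.fit(des$X2, des$y2, family = binomial())$coefficients
  expect_equal(unname(fit$theta1), unname(g1), tolerance = 0.02)
  expect_equal(unname(fit$theta2), unname(g2), tolerance = 0.02)
  # truth recovery within 3 reported SEs
  se1 <- fit$se[paste0("stunted:", names(fit$theta1))]
  truth_th1 <- truth$theta1[names(fit$theta1)]
  expect_true(all(abs(fit$theta1 - truth_th1) < 3 * se1 + 1e-8))
})

test_that("estimates are invariant to cluster ordering", {
  cohort <- small_cohort(n_clusters = 40, mean_children = 5, seed = 73)
  des <- build_stacked_design(cohort, "fever")
  cfg <- analysis_config(nodes = 7)
  fit <- fit_joint_model(des, cfg)
  set.seed(1)
  perm <- sample(nrow(cohort))
  des_p <- build_stacked_design(cohort[perm, ], "fever")
  fit_p <- fit_joint_model(des_p, cfg)
  expect_equal(fit$theta1, fit_p$theta1, tolerance = 1e-8)
  expect_equal(fit$sigma, fit_p$sigma, tolerance = 1e-8)
  expect_equal(fit$loglik, fit_p$loglik, tolerance = 1e-8)
})

test_that("the univariate AGQ fit matches lme4::glmer at the same node count", {
  skip_if_not_installed("lme4")
  cohort <- small_cohort(n_clusters = 60, mean_children = 6, seed = 79,
                         Sigma = make_sigma(0.8, 0.8, 0.4))
  des <- build_stacked_design(cohort, "fever")
  cfg <- analysis_config(nodes = 7)
  indep <- fit_independent_models(des, cfg)
  df <- data.frame(y = des$y1, fever = des$X1[, 2], cl = des$cl1)
  gm <- lme4::glmer(y ~ fever + (1 | cl), data = df, family = binomial,
                    nAGQ = 7)
  expect_equal(unname(indep$fits[[1]]$theta), unname(lme4::fixef(gm)),
               tolerance = 2e-3)
  expect_equal(indep$fits[[1]]$sigma2,
               unname(lme4::VarCorr(gm)$cl[1, 1]), tolerance = 5e-3)
  expect_equal(indep$fits[[1]]$loglik, as.numeric(logLik(gm)),
               tolerance = 1e-3)
})

test_that("the joint Laplace fit matches glmmTMB's unstructured bivariate fit", {
  skip_if_not_installed("glmmTMB")
  cohort <- small_cohort(n_clusters = 80, mean_children = 6, seed = 83,
                         Sigma = make_sigma(0.8, 0.8, 0.5))
  des <- build_stacked_design(cohort, "fever")
  cfg <- analysis_config(nodes = 1)
  fit <- fit_joint_model(des, cfg)
  long <- rbind(
    data.frame(y = des$y1, fever = des$X1[, 2], cl = des$cl1, outc = "st"),
    data.frame(y = des$y2, fever = des$X2[, 2], cl = des$cl2, outc = "an"))
  tmb <- glmmTMB::glmmTMB(y ~ 0 + outc + outc:fever + (0 + outc | cl),
                          data = long, family = binomial)
  vc <- glmmTMB::VarCorr(tmb)$cond$cl
  expect_equal(fit$loglik, as.numeric(logLik(tmb)), tolerance = 1e-3)
  expect_equal(unname(fit$sigma["sigma11"]), unname(vc["outcst", "outcst"]),
               tolerance = 0.02)
  expect_equal(unname(fit$sigma["sigma22"]), unname(vc["outcan", "outcan"]),
               tolerance = 0.02)
  expect_equal(unname(fit$sigma["sigma12"]), unname(vc["outcst", "outcan"]),
               tolerance = 0.02)
})
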