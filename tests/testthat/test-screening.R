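test_that("crosstab cells match raw counts and scale with weights", {
  counts <- matrix(c(184, 416, 160, 537), 2, 2, byrow = TRUE,
                   dimnames = list(c("Male", "Female"), c("yes", "no")))
  rec <- validate_child_records(
    records_from_counts(counts, "sex", "stunted"))
  xt <- weighted_crosstab(rec, "sex", "stunted", use_weights = FALSE)
  expect_equal(xt$counts[rownames(counts), ], counts)
  # doubling every weight doubles cells, leaves row percentages unchanged
  rec2 <- rec
  rec2$weight <- 2
  xt2 <- weighted_crosstab(rec2, "sex", "stunted", use_weights = TRUE)
  expect_equal(xt2$counts, 2 * xt$counts)
  expect_equal(xt2$row_pct, xt$row_pct)
})

test_that("crosstab rejects degenerate inputs", {
  rec <- tiny_records()
  rec$stunted <- c(1L, 0L, 1L)
  rec$onelevel <- "A"
  expect_error(weighted_crosstab(rec, "onelevel", "stunted"),
               "single observed level")
  rec$stunted <- NA_integer_
  expect_error(weighted_crosstab(rec, "fever", "stunted"), "empty table")
})

test_that("published contingency tables reproduce their printed p-values", {
  # sex x stunting
  sex <- matrix(c(184, 416, 160, 537), 2, 2, byrow = TRUE)
  r1 <- chi2_test(sex)
  expect_equal(r1$statistic, 9.84, tolerance = 1e-3)
  expect_identical(r1$df, 1L)
  expect_equal(round(r1$p_value, 3), 0.002)
  # fever x anaemia
  fever <- matrix(c(120, 71, 493, 449), 2, 2, byrow = TRUE)
  r2 <- chi2_test(fever)
  expect_equal(r2$statistic, 7.04, tolerance = 1e-3)
  expect_equal(round(r2$p_value, 3), 0.008)
})

test_that("proportional tables give a zero statistic", {
  r <- chi2_test(matrix(c(50, 50, 100, 100), 2, 2, byrow = TRUE))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("chi2_test agrees with the 2x2 closed form on random tables", {
  set.seed(31)
  for (i in 1:50) {
    m <- matrix(rpois(4, lambda = sample(5:80, 1)) + 1, 2, 2)
    expect_equal(chi2_test(m)$statistic, chi2_2x2_closed(m),
                 tolerance = 1e-10)
  }
  # weighted, non-integer counts work identically
  m <- matrix(c(12.4, 33.1, 25.8, 19.7), 2, 2)
  expect_equal(chi2_test(m)$statistic, chi2_2x2_closed(m), tolerance = 1e-10)
})

test_that("zero expected cells are rejected with merge advice", {
  expect_error(chi2_test(matrix(c(0, 10, 0, 20), 2, 2)), "merge")
})

test_that("screening applies the strict p < alpha union rule", {
  # variable A: associated with stunting (p ~ 0.02), balanced for anaemia
  a_st <- matrix(c(70, 30, 50, 50), 2, 2, byrow = TRUE,
                 dimnames = list(c("Yes", "No"), NULL))
  rec <- records_from_counts(a_st, "fever", "stunted")
  set.seed(41)
  rec$anaemic <- rep(c(0L, 1L), length.out = nrow(rec))  # exactly balanced
  # variable B: balanced for both (period-4 pattern is orthogonal to the
  # alternating anaemia assignment)
  rec$cough <- rep(c("Yes", "No", "No", "Yes"), length.out = nrow(rec))
  rec <- validate_child_records(rec)
  sc <- screen_covariates(rec, variables = c("fever", "cough"), alpha = 0.2,
                          use_weights = FALSE)
  expect_true("fever" %in% sc$retained$stunted)
  expect_false("fever" %in% sc$retained$anaemic)
  expect_identical(sc$union, "fever")
  expect_false("cough" %in% sc$union)
  # strictness: alpha exactly at the p-value does not retain
  p_fever <- sc$table$p_value[sc$table$variable == "fever" &
                              sc$table$outcome == "stunted"]
  sc2 <- screen_covariates(rec, variables = "fever", alpha = p_fever,
                           use_weights = FALSE)
  expect_false("fever" %in% sc2$retained$stunted)
})

test_that("screening has power ~1 for a strong effect and level ~alpha under the null", {
  set.seed(43)
  n <- 3000
  hits <- 0L
  for (r in 1:100) {
    x <- sample(c("Yes", "No"), n, replace = TRUE)
    eta <- -0.5 + 1.0 * (x == "No")
    rec <- data.frame(child_id = as.character(1:n), cluster_id = "A",
                      household_id = "h", weight = 1, fever = x,
                      stunted = as.integer(runif(n) < plogis(eta)),
                      anaemic = rep(0:1, length.out = n))
    sc <- screen_covariates(validate_child_records(rec), variables = "fever",
                            alpha = 0.2, use_weights = FALSE)
    if ("fever" %in% sc$union) hits <- hits + 1L
  }
  expect_gte(hits, 99L)

  # type-I error of the retention rule at alpha = 0.2 under no effect
  set.seed(47)
  n <- 500
  rejections <- 0L
  for (r in 1:500) {
    m <- matrix(c(sum(runif(n / 2) < 0.5), sum(runif(n / 2) < 0.5)), 1)
    tab <- rbind(c(m[1], n / 2 - m[1]), c(m[2], n / 2 - m[2]))
    if (chi2_test(tab)$p_value < 0.2) rejections <- rejections + 1L
  }
  rate <- rejections / 500
  expect_gt(rate, 0.2 - 3 * sqrt(0.2 * 0.8 / 500))
  expect_lt(rate, 0.2 + 3 * sqrt(0.2 * 0.8 / 500))
})

test_that("required sample size follows z^2 p (1-p) / d^2", {
  expect_equal(required_sample_size(0.5)$n, 384.16)
  expect_equal(required_sample_size(0.51)$n, 1.96^2 * 0.51 * 0.49 / 0.05^2)
  expect_equal(required_sample_size(0.51)$n, 384.0063, tolerance = 1e-6)
  expect_identical(required_sample_size(0.5)$n_ceiling, 385)
  expect_equal(required_sample_size(0)$n, 0)
  expect_error(required_sample_size(0.5, d = 0), "positive")
})
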