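---
title: "Joint modelling of childhood anaemia and stunting: methods"
author: "bivglmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of childhood anaemia and stunting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivglmm)
```

## The scientific problem

Anaemia (low haemoglobin) and stunting (chronic growth failure) co-occur in
young children, and surveys such as the Demographic and Health Surveys (DHS)
measure both on the same child. Modelling each outcome separately cannot say
anything about their association. `bivglmm` implements a joint analysis of
the two binary outcomes in which each child `i` in cluster `c` contributes a
pair of Bernoulli responses,

```
logit P(stunted_ic = 1 | u_c) = x_ic' theta_1 + u_c1
logit P(anaemic_ic = 1 | u_c) = x_ic' theta_2 + u_c2
(u_c1, u_c2)' ~ iid MVN(0, Sigma),   Sigma = [sigma11 sigma12; sigma12 sigma22]
```

with separate fixed-effect vectors per outcome and an unstructured 2x2
covariance for the paired cluster-level random intercepts. The off-diagonal
`sigma12` carries the scientific question: it links the outcomes, and
`sigma12 = 0` reduces the joint model to two ordinary per-outcome GLMMs.

## Grouping level of the random effects

The random-effect pairs are placed at the *cluster* (enumeration-area)
level. With one pair per cluster, `sigma11` and `sigma22` are identified by
within-cluster correlation of each outcome and `sigma12` by the
between-outcome association of cluster summaries. A child-level pairing
would make the variances weakly identified from single binary observations;
we therefore do not offer it as a default.

## Estimation

The marginal likelihood integrates the paired random effects out of each
cluster's contribution:

```
ll = sum_c log Int prod_i prod_k Bernoulli(y_ick; expit(x_ic' theta_k + u_k)) phi(u; 0, Sigma) du
```

The 2-D integral is evaluated by *adaptive Gauss-Hermite quadrature* (AGQ):
for each cluster the integrand's mode is found by Newton iterations, the
quadrature grid is centred at the mode and scaled by the Cholesky factor of
the inverse curvature, and a tensor product of `nodes` (default 7)
Gauss-Hermite points per dimension is summed in log space. One node
recovers the Laplace approximation. The implementation is compiled (C++)
because the likelihood is evaluated thousands of times per fit.

Direct maximum likelihood with AGQ is a deliberate design choice. The
linearization-based pseudo-likelihood used by some mixed-model software is
known to bias variance components for binary responses; published
coefficient tables produced that way are therefore treated as *transform
checks* (odds-ratio arithmetic) and as a source of simulation ground truth,
not as numbers a correct ML fit must reproduce.

Numerical choices:

* `Sigma` is parameterized by its log-Cholesky factor
  `L = [[exp(l1), 0], [l21, exp(l2)]]`, so the optimization is
  unconstrained and `Sigma = LL'` is positive definite by construction.
  The diagonal log terms are clamped to `[-8, 5]`, which brackets variances
  from ~1e-7 to ~2e4 — in effect allowing boundary fits without numerical
  overflow.
* Starting values: per-outcome logistic fits without random effects for the
  fixed effects, `0.1 * I` for `Sigma`. The pipeline additionally
  warm-starts the joint fit from the independence fit, which guarantees the
  nested optimum is never left behind on a flat covariance surface.
* Optimizer: BFGS with central finite-difference gradients, run twice, then
  polished with damped Newton steps using the observed information until
  the gradient norm reaches the configured tolerance (`1e-5` by default).
  The convergence flag also accepts a likelihood-scaled gradient criterion
  (`1e-5 * |ll|`), since an absolute 1e-5 gradient norm is not always
  attainable with finite-difference derivatives on several thousand
  observations.
* Standard errors come from the inverse observed information at the
  optimum, delta-transformed from the log-Cholesky scale to
  `(sigma11, sigma12, sigma22)`.
* Degenerate covariances in likelihood *evaluation* are handled by
  collapsing dimensions: a zero variance removes that outcome's integral; a
  singular but nonzero `Sigma` (perfect correlation) is integrated along
  its one free direction. The *fitter* never visits these cases because the
  log-Cholesky parameterization keeps `Sigma` positive definite.
* Clusters observed for only one outcome still contribute a 2-D integral
  (flat in the unobserved direction apart from the prior); children missing
  one outcome contribute their other row.
* Negative LRT statistics as large as `1e-3` are clamped to zero rather
  than raised as errors: with boundary-adjacent variance estimates the
  nested and full optimizers can land within ~1e-5 log-likelihood units of
  each other on the wrong side. Anything beyond that indicates a genuine
  optimizer failure and is an error.

## Outcome derivation

* Haemoglobin is adjusted for altitude with the CDC polynomial used by the
  DHS program: with `A` the altitude in thousands of feet, the adjustment
  `max(0, -0.032 A + 0.022 A^2)` g/dl is subtracted from the measured
  value. The source analysis only states that an adjustment was applied;
  the CDC/DHS convention is adopted and can be replaced by pre-adjusting
  the input column.
* Anaemia: adjusted haemoglobin `< 11` g/dl (strict), with severity bands
  `< 7` (severe), `[7, 9)` (moderate), `[9, 11)` (mild). The half-open
  intervals make the printed band edges ("between 7 and 8.9", "between 9
  and 10.9") exhaustive on a continuous scale.
* Stunting: HAZ `< -2` SD (strict). A severe flag at `< -3` SD is exposed
  for completeness (the conventional severe cutoff), but the joint model
  consumes only the binary indicator.
* Children under 6 months are excluded from anaemia derivation (flagged
  missing), mirroring the survey protocol; the HAZ-based outcome is
  unaffected.

## Screening stage

Covariates are screened one at a time against each outcome with Pearson
chi-square tests on weighted crosstabs (cells are sums of sampling
weights). A variable enters the joint model when `p < 0.2` (strict) for
*either* outcome. Two caveats are deliberate: summed-weight chi-square
without a design-effect correction reproduces a common SPSS-style workflow
but is not design-based inference, and the joint model itself is fitted
unweighted by default (`use_weights` in `build_stacked_design()` enables a
weighted pseudo-likelihood). The classical `n = z^2 p (1-p) / d^2` sample
size formula is provided as `required_sample_size()`.

## Hypothesis tests on the covariance structure

* `sigma12 = 0` is an *interior* null whenever both variances are positive,
  so the LRT `2 (ll_joint - ll_independent)` is referred to chi-square(1).
  Wald (`(sigma12_hat / SE)^2`) and score versions are exposed as options;
  the LRT is the default for reproducibility.
* A variance `sigma_kk = 0` sits on the *boundary* of its parameter space;
  the LRT against the no-random-effect logistic fit uses the 50:50 mixture
  of a point mass at zero and chi-square(1). The mixture p-value is never
  larger than the naive chi-square(1) p-value, so the naive test is
  conservative.

## Goodness of fit

The grouped Pearson statistic compares, within each covariate pattern, the
observed proportions in the two response categories with the model's
marginal fitted probabilities `E[expit(x'theta_k + u)]` (computed by
quadrature over the fitted random-effect distribution), summed over both
outcomes. Degrees of freedom are patterns minus free parameters; the
statistic/df ratio above a configurable bound (default 1.2) flags possible
overdispersion. With continuous or many-levelled covariates, patterns
become sparse and the chi-square reference is unreliable — the verdict is a
diagnostic, not a test.

## The synthetic cohort generator

The restricted survey microdata cannot be shipped, so every stage is
exercised against a generator that draws from exactly the model above with
known ground truth:

* ~400 clusters with Poisson(8) children each (truncated at 1), matching
  the source survey's ~3,100 children over 400 enumeration areas; children
  are 6-59 months old (the anaemia-eligible range).
* Covariates are drawn independently across variables with category
  probabilities near the published univariate tables; no joint covariate
  distribution is published, so none is emulated.
* Default fixed effects are the published joint-model point estimates, with
  one sign corrected from its printed odds ratio (age under 20 months,
  stunting: OR 0.436 implies -0.829, not +0.829). Intercepts are calibrated
  so the mean-covariate linear predictor hits the published prevalences
  (43% stunting, 51% anaemia).
* The default covariance uses the published variances
  `sigma11 = 0.104`, `sigma22 = 0.314` with the cross covariance capped at
  the positive-semidefinite boundary `sqrt(sigma11 sigma22) ~ 0.181`: the
  printed covariance estimate of 1.000 is incompatible with the printed
  variances (1.000^2 > 0.104 x 0.314), an anomaly we surface rather than
  silently reproduce. Studies of covariance recovery instead use
  variances of ~1 so the printed covariance is admissible.
* Sampling weights are lognormal with mean 1 (sdlog 0.35) — heavier-tailed
  than calibrated survey weights but positive and right-skewed; the
  two-stage PPS selection mechanics of a real DHS are not emulated.
* Biomarker backfill draws adjusted-scale haemoglobin from truncated
  normals strictly below/above the anaemia cutoff according to the
  simulated flag, adds back the altitude adjustment for a uniform
  1,400-3,400 m altitude (the Lesotho highlands), and draws HAZ around the
  -2 SD cutoff the same way, so derive-after-backfill reproduces the
  simulated outcomes exactly (small 1e-6 guard margins absorb floating
  point error).
* One seed drives everything through fixed per-stage offsets
  (sizes/covariates, random effects, outcomes, weights, biomarkers), so
  stages are independently reproducible.

What passing tests on this generator do *not* show: robustness to
informative weights, correlated covariates, spatially structured random
effects, or misclassification in the biomarkers — real-data features the
generator deliberately omits.

## Problem sizes used in the checks

The test suite fits the joint model at the survey scale (400 clusters,
~3,200 children) for parameter-recovery checks (5 replicates, mean
recovered `sigma12` within 0.1 of truth), and calibrates the size of the
covariance LRT on 500 intercept-only replicates of 100 clusters x ~6
children — large enough for the interior-null chi-square asymptotics to
hold while keeping each replicate's three fits under a second. Likelihood
correctness is checked against dense-grid integration oracles on 2-3
cluster instances, where brute force is exact to ~1e-8.

## Known limitations

* Exactly two outcomes; no crossed or nested random effects beyond the
  single cluster level.
* Unweighted ML is the default; the weighted option is a pseudo-likelihood
  whose variance estimates do not account for the sampling design.
* The score test evaluates numerical derivatives at the independence fit
  and is the slowest of the three covariance tests.
* The published analysis reports several internally inconsistent numbers
  (analysis denominators, two coefficient/OR mismatches, a statistic/df
  ratio printed as degrees of freedom). The pipeline reports its own
  denominators and treats only internally consistent rows as checkable
  arithmetic.
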