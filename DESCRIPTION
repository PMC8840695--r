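Package: bivglmm
Title: Joint Bivariate Logistic Mixed Models for Child Anaemia and Stunting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint analysis of two correlated binary child-health outcomes
    (anaemia and stunting) in survey-structured data. Provides derivation of
    the binary outcomes from haemoglobin (with altitude adjustment) and
    height-for-age z scores, weighted contingency-table screening, maximum
    likelihood estimation of a bivariate logit generalized linear mixed model
    with cluster-level random intercepts linked by an unstructured 2x2
    covariance (adaptive Gauss-Hermite quadrature), boundary-aware tests for
    variance and covariance components, grouped Pearson goodness-of-fit, and
    odds-ratio reporting. Includes a synthetic DHS-like cohort generator with
    known ground truth so the whole pipeline is testable without restricted
    survey microdata.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmmTMB,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
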