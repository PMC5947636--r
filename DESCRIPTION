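Package: cycmsm
Title: Marginal Structural Models for Cyclophosphamide Efficacy in
    Juvenile Dermatomyositis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for estimating the causal effect of a
    noncontinuous cyclophosphamide treatment course on skin (DAS), global
    (PGA) and muscle (CMAS) disease activity in juvenile dermatomyositis
    cohorts with time-varying confounding by indication.  Implements the
    probability-of-treatment model (baseline receipt, initiation and
    discontinuation sub-models), stabilized inverse
    probability-of-treatment weights with truncation, multiple imputation
    of missing scores by chained equations with Rubin pooling, weighted
    longitudinal outcome models with a treatment-recency ("split time")
    covariate, an unadjusted descriptive battery (chi-square, Fisher,
    rank tests, Friedman repeated measures), covariate-balance
    diagnostics, and a synthetic cohort generator emulating
    severity-driven treatment initiation for validation by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    sandwich,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
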