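Package: uricbn
Title: Metabolic-Obesity Phenotyping and Bayesian-Network Analysis of
    Hyperuricemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying sex-specific associations between
    metabolic-health/obesity phenotypes and hyperuricemia in adult
    cohorts.  Derives the six metabolic-obesity phenotypes (MHNW, MHOW,
    MHO, MUNW, MUOW, MUO) from raw anthropometric and biochemical
    measurements using ATP-III and Visceral Adiposity Index criteria,
    computes sex-specific prevalences with Wilson intervals and
    sequentially adjusted logistic odds-ratio tables, and learns discrete
    Bayesian networks from the phenotyped data by Tabu search with BIC
    scoring, bootstrap arc-strength model averaging, and exact
    conditional-probability reasoning.  A seeded synthetic-cohort
    generator calibrated to published marginal and conditional structure
    supports simulation studies and parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
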