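Package: grsmr
Title: Genetic Risk Scores and Mendelian Randomization for Coded
    Biobank Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for causal inference on electronic-health-record
    derived phenotypes in biobank-scale cohorts. Implements derivation of
    nested case/control definitions from diagnosis, procedure and
    self-report code lists; greedy selection of an unrelated sample from
    kinship pairs; weighted genetic risk score construction with allele
    harmonization and instrument-strength diagnostics; covariate-adjusted
    observational association models with rank-based inverse-normal
    transforms; one-sample Mendelian randomization by two-stage
    instrumental-variable estimation with a binary outcome, per-unit
    effect rescaling and an analytic power calculator; and two-sample
    summary-statistic Mendelian randomization (Wald ratios,
    inverse-variance weighted, MR-Egger, weighted median) with
    heterogeneity diagnostics. A configurable cohort simulator with known
    generative parameters (pleiotropy, confounding, code
    sensitivity/specificity, relatedness) supports validation of every
    stage without access to restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
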