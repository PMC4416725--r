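Package: prspipe
Title: Weighted Polygenic Risk Score Modelling for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for weighted polygenic risk score (PRS)
    analysis of case-control genotype data, motivated by multi-locus risk
    prediction in psoriasis. Reads PLINK text genotypes, variant weight
    panels and phenotype tables; performs per-sample and per-variant quality
    control (call rates, Hardy-Weinberg exact test in controls) and allelic
    chi-square association tests; computes ln(odds-ratio)-weighted risk
    scores under nested variant panels with an optional environmental
    exposure term; bins subjects by control-quartile score groups and fits
    covariate-adjusted logistic risk models; compares model discrimination
    by ROC curves with DeLong's test for paired AUCs; and analyses age of
    onset by Kaplan-Meier curves, log-rank tests and Cox proportional
    hazards models. A calibrated synthetic-cohort generator with a
    retrospective case-control sampling scheme makes every stage testable
    without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
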