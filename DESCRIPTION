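Package: polybench
Title: Benchmarking Smooth-Threshold and Penalized Polygenic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation benchmark for polygenic prediction of quantitative
    traits. Provides a heritability-controlled GWAS phenotype simulator with
    normal, Laplace and normal-exponential-gamma effect-size distributions;
    the smooth-threshold multivariate genetic prediction (STMGP) estimator, a
    generalized ridge regression with marginal-association-adaptive penalty
    weights and a Mallows' Cp-selected P-value screening cutoff; baseline
    predictors (P-value-threshold polygenic scores with LD clumping, GBLUP
    via REML variance components, summary-statistic BLUP, and ridge
    regression on clumped markers); PLINK1 binary genotype input/output with
    standard sample and variant quality control; and the evaluation
    statistics used to compare predictors (predictive and partial
    correlations, Williams' test for dependent correlations, calibration
    slope, and replicate power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
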