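Package: mvmrq
Title: Weak-Instrument and Pleiotropy Robust Two-Sample Multivariable
    Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample multivariable Mendelian randomization (MVMR)
    with GWAS summary statistics. Implements the conditional instrument-strength
    test based on the two-sample conditional F-statistic with Stock-Yogo-type
    critical values, an exact weak-instrument-robust heterogeneity (pleiotropy)
    test based on minimization of the Q_A statistic, causal-effect estimators
    that are robust to weak instruments (beta_Q) and additionally to balanced
    pleiotropy (beta_Q,het with a pleiotropy variance parameter), jackknife
    standard errors, three routes for constructing the per-SNP covariance of
    SNP-exposure estimation errors (individual-level data, phenotypic
    correlation, or zero), and calibrated Monte-Carlo simulation designs for
    validating all of the above end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
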