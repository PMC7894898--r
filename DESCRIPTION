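Package: scmmst
Title: Mixed-Model Score Tests for Zero-Inflated Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression testing for single-cell RNA-seq count
    data with batch effects and excess zeros. Batches are modelled as random
    intercepts in a generalized linear mixed model (Poisson, quasi-Poisson or
    negative binomial), and a variance-component score statistic is tested
    against its mixture chi-square null distribution via exact
    characteristic-function inversion. Excess zeros are handled through
    observational weights estimated under zero-truncated or zero-inflated
    count models (truncated Poisson, zero-inflated Poisson, truncated negative
    binomial, or a zero-inflated negative binomial regression with batch fixed
    effects). Includes a GLMM-based simulator of multi-batch single-cell
    counts with logit-linked dropout, and evaluation utilities (per-comparison
    error rate, FDP-TPR curves, ROC AUC, Benjamini-Hochberg adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    Matrix,
    MASS,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
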