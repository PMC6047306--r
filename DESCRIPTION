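Package: bssr
Type: Package
Title: Estimation After Blinded Sample Size Reassessment in Two-Stage Trials
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation and inference for two-stage parallel-group superiority
    trials with blinded sample size reassessment based on the one-sample
    (lumped) interim variance. Implements the blinded interim variance
    estimator, the unadjusted and adjusted reassessment rules, final point
    estimates and t-based confidence bounds, exact numerical evaluation of the
    bias of the final mean and variance estimators by nested quadrature,
    worst-case (oracle) reassessment rules with sharp and unblinded bias
    bounds, closed-form bounds for the variance-estimator bias, a vectorized
    Monte-Carlo engine for bias and coverage surfaces, and staged grid
    maximization of bias and non-coverage over the true effect size and
    standard deviation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
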