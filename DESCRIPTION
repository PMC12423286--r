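Package: crowtime
Title: Interval-Timing Behavior and Neural Population Analysis for Avian Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing interval-timing experiments in which subjects
    are cued to wait one of several target durations before responding, with
    simultaneous single-unit recordings. Provides a synthetic session generator
    (behavioral reaction times with scalar variability and inhomogeneous Poisson
    spike trains from parameterised neuron archetypes), behavioral Gaussian fits
    of reaction-time histograms, single-unit duration-selectivity statistics
    (two-way ANOVA, tuning curves and widths, Jonckheere-Terpstra trend test,
    ramping model fits, temporal-scaling grid search), pseudopopulation linear
    SVM decoding (within- and cross-protocol generalization, elapsed-time and
    error-trial decoding, cross-temporal matrices with cluster permutation
    significance), omega-squared percent-explained-variance time courses, and
    PCA state-space trajectory geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    glmnet,
    withr
Config/testthat/edition: 3
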