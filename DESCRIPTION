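Package: swmediate
Title: Sampling-Weighted Causal Mediation Analysis via Cross-World Weights
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Weighting-based estimation of natural direct and indirect
    effects (cross-world mediation weights built from two propensity
    models) for samples drawn with unequal selection probabilities.
    Implements four strategies for incorporating sampling weights into
    the analysis (in neither stage, in the propensity/weight-estimation
    stage, in the outcome stage, or in both), together with a synthetic
    population generator with all-binary exposure, mediator, outcome and
    covariates, unequal-probability samplers, exact and Monte-Carlo
    computation of true effects, and a replication-study harness that
    reports bias, relative bias, MSE, mean standard error and empirical
    standard deviation for every effect under every condition.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
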