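Package: infodemand
Title: Simulation and Analysis of Information Demand in Two-Lottery Sampling Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people prioritize informative observations
    when predicting the combined payoff of two lotteries. Implements the task
    generator (two-prize lotteries with high and low variance and a constant
    total expected value), a normative observer that enumerates post-reveal
    outcomes and expected earnings, a synthetic-cohort simulator with labelled
    sampling strategies and planted personality associations, maximum a
    posteriori fitting of bivariate and univariate psychometric choice models
    with BIC-based strategy classification, model-free behavioural metrics
    including Hartigan's dip test of multimodality, and bootstrap decoding of
    sampling efficiency from personality profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
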