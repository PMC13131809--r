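Package: ssdprior
Title: Bayesian and Category-Learning Models of Trans-Saccadic Visual
    Stability Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analyses for saccadic suppression of displacement
    (SSD) experiments in which subjects report whether a visual probe
    jumped during an eye movement under cued prior probabilities and
    manipulated saccade-driven and image noise. Implements a Bayesian
    ideal observer with a non-central chi-square decision rule, a
    two-layer perceptron-like category-learning network with
    prior-specific population-code inputs, their weighted combination,
    maximum-likelihood fitting of the combined model to binary session
    responses, firing-rate analyses (z-score normalization, Wilcoxon
    rank-sum effect sizes, sliding-bin screens, mixed-effects regression
    designs) that dissociate Bayesian from anti-Bayesian prior use, and
    synthetic-data generators for behavioral sessions and model neurons
    so the full pipeline runs without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
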