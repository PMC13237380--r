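Package: safeval
Title: Safety-Value Reinforcement Learning and Photometry Analysis for
    Active-Avoidance Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-way active-avoidance experiments in
    which animals learn the value of action-derived safety. Implements a
    Rescorla-Wagner model of avoidance probability with group-level
    least-squares fitting, subject-level bootstrap standard errors and
    label-permutation tests on fitted parameters, a hierarchical Bayesian
    individual-subject model with split-R-hat diagnostics and parameter
    recovery, the fiber-photometry processing chain (isosbestic
    detrending, dF/F, peri-event alignment, baseline z-scoring, trapezoid
    AUC, dual-sensor peak-offset analysis), behavioural metrics
    (avoidance rate, progressive-ratio breakpoint), ex vivo
    electrophysiology scalar metrics, and synthetic-data generators for
    task schedules, avoidance learners and two-channel photometry so
    every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
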