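Package: glycolearn
Title: Glucose Tolerance and Reward Learning Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking oral-glucose-tolerance dynamics to
    reinforcement-learning parameters. Simulates probabilistic-selection-task
    behaviour and continuous-glucose-monitor traces with known ground truth,
    computes incremental area under the glucose curve with baseline-crossing
    interpolation, fits hierarchical Bayesian Q-learning models (single and
    dual learning rate) by gradient-based MCMC with full convergence
    diagnostics, compares models by Pareto-smoothed importance-sampling
    leave-one-out cross-validation, and estimates posterior distributions of
    parameter-covariate correlations with highest-density intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
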