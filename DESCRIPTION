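Package: ventriloquo
Title: Causal-Inference Observer Models for Audiovisual Ventriloquism Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for categorical audiovisual
    localization experiments of the ventriloquism family. Implements seven
    ideal-observer models (Bayesian causal inference with model averaging,
    probability matching, or model selection; forced fusion and segregation
    with or without a Gaussian location prior), Monte-Carlo prediction of
    binned button-response distributions, a three-step multinomial
    maximum-likelihood fitting pipeline with grid-search initialization,
    bounded quasi-Newton refinement and BIC model comparison, trial-sequence
    generation for the two-block design (factorial discrepancies, then a
    constant 10 degree discrepancy), ventriloquism effect and immediate and
    cumulative aftereffect statistics with Welch ANOVA, Games-Howell and
    Holm-corrected one-sample tests, and a synthetic observer-cohort
    generator for parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
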