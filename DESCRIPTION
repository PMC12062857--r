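Package: volbandit
Title: Reinforcement Learning Under Volatility: Task Simulation, Hierarchical
    Bayesian Model Fitting and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying reward learning under stable and volatile
    reward contingencies with a two-option probabilistic bandit ("two pirates")
    task. Generates exact-ratio reward schedules, simulates choice behaviour
    from a twelve-member family of reinforcement-learning models
    (Rescorla-Wagner with phase-specific learning rates, softmax exploration,
    starting bias, optional magnitude utility, win-stay-lose-shift and null
    models), fits participants individually by penalised maximum a posteriori
    estimation and jointly by a non-centered hierarchical Bayesian sampler,
    compares models by WAIC and K-fold cross-validation with a
    participant-level null-model exclusion rule, and provides the cohort-level
    statistics used in developmental studies of this task: pooled t tests,
    retention chi-square, Mann-Whitney U, noncentral-t power and sensitivity
    analysis, and longitudinal moderation regression with part correlations.
    Includes a synthetic-cohort generator with group structure, random
    responders and longitudinal symptom outcomes for recovery testing, and a
    seeded multi-stage analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
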