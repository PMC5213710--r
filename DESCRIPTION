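Package: relmrs
Title: Reward-Effort Learning Models and Neurochemical Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, fitting and comparison of Rescorla-Wagner
    reinforcement-learning models of a probabilistic reward/effort
    learning task, together with the statistical machinery linking model
    parameters to magnetic resonance spectroscopy (MRS) measures of
    glutamate and GABA. Provides a seeded task-schedule and agent
    simulator, hierarchical Bayesian (MCMC) and maximum-likelihood model
    fitting, BIC and half-split cross-validation model comparison,
    parameter-recovery studies, lagged stay/switch logistic-regression
    behavioral validation, creatine normalisation and partial-volume
    correction of MRS measures, and nonparametric (Spearman) partial
    correlations with covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
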