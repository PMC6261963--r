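Package: placeboRL
Title: Hierarchical Bayesian Reinforcement-Learning Analysis of
    Placebo and Nocebo Effects on Instrumental Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing reward-based
    instrumental learning experiments with expectancy (placebo/nocebo)
    manipulations. Provides a generative simulator of a three-pair
    probabilistic selection task with counterbalanced schedules and
    manipulated reward contingencies, dual-learning-rate Q-learning
    agents with a softmax choice rule, hierarchical Bayesian estimation
    of the model parameters (probit-normal learning rates, log-normal
    exploration parameter, shrunken day-by-group effects) via
    Hamiltonian Monte Carlo with analytic gradients, Pareto-smoothed
    importance-sampling leave-one-out model comparison (LOOIC),
    hierarchical accuracy/reaction-time regressions and a
    three-category softmax regression for subjective performance
    reports, and desk-scale parameter- and model-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    coda,
    rjags,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
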