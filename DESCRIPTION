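Package: resistmap
Title: Geostatistical Ensemble Mapping of Insecticide Resistance Phenotypes
Version: 0.1.0
Authors@R:
    person("resistmap", "developers", email = "resistmap@example.org",
           role = c("aut", "cre"))
Description: Bayesian geostatistical stacked-generalization modelling of the
    prevalence of insecticide resistance in mosquito populations over space
    and time. Provides a label transformation chain (empirical logit followed
    by inverse hyperbolic sine) for binomial bioassay mortality data, three
    machine-learning level-0 learners (gradient-boosted trees with dropout
    regularization, bagged trees with random feature subsetting, and a
    componentwise-boosted additive model), a Gaussian-process meta-model with
    nonnegative model weights and a separable spatiotemporal Gaussian Markov
    random field, out-of-sample validation with credible-interval coverage
    and probability integral transform diagnostics, map summary statistics,
    and a seed-deterministic synthetic-data generator emulating heterogeneous
    bioassay sampling so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    splines,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
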