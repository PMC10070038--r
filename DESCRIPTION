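Package: binpower
Title: Power and Sample Size for Genetic Association Studies of Binary Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Power and sample size computation for testing the association
    between a genetic variant and a binary trait via logistic regression,
    with explicit adjustment for non-genetic covariate effects and for
    gene-environment dependence modelled through second-stage regressions.
    Implements two estimators of the unconditional Fisher information -- a
    scalable semi-simulation estimator whose cost is independent of the
    target sample size, and a deterministic expanded representative-dataset
    estimator -- together with a full-simulation empirical-power benchmark
    (simulate, fit, Wald test) for validation, and sample-size inversion of
    the monotone power function. Supports prospective and retrospective
    case-control designs, additive/dominant/recessive genotype codings under
    Hardy-Weinberg equilibrium, and binary or continuous covariates with
    automatically gleaned intercepts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
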