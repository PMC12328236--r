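Package: perturblm
Title: Linear Baselines and Benchmarks for Perturbation Effect Prediction
Version: 0.1.0
Authors@R:
    person("Benchmark", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Baseline prediction models, genetic-interaction statistics and an
    evaluation framework for single- and double-perturbation transcriptomics
    (Perturb-seq style data). Implements the no-change, mean, additive and
    bilinear ridge linear models, gene and perturbation embeddings (training
    PCA, spectral embedding of pathway membership, reference-data PCA,
    external tables, random draws), an empirical-null decomposition of
    deviations from the additive expectation with FDR-controlled interaction
    calling and classification, FDP-TPR benchmark curves, bootstrap
    relative-error confidence intervals, a seeded synthetic-data generator
    with known ground truth, and a command-line pipeline that can also score
    arbitrary external predictors supplied as prediction matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
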