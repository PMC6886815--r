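Package: mlmapper
Title: Machine Learning Morphism Workflows with Mapper-Based Local Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A composable framework for building machine learning workflows
    as risk-minimizing morphisms, together with its flagship application: a
    TDA-Mapper-based ensemble binary classifier for imbalanced mixed-type
    tabular data. Provides the morphism abstraction (fit by empirical risk
    minimization, composition, decomposable direct sums, collections), a
    from-scratch Mapper implementation (principal-component filtration,
    overlapping interval covers, Gower k-medoids clustering, node pruning,
    exact graph edit distance), class-imbalance resampling (SMOTE and a
    smoothed-bootstrap ROSE variant), per-node local model pipelines with
    convex node weighting, threshold selection on pooled cross-validation
    scores, seeded synthetic cohort generators, and a repeated-holdout
    evaluation protocol with a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    FNN,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
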