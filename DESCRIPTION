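Package: phytoscreen
Title: Predicting Medicinal Uses of Natural Compounds from Heterogeneous Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens plant-derived natural compounds for candidate medicinal
    uses by integrating three heterogeneous feature blocks: latent-knowledge
    features composed from sub-word (character n-gram) embeddings of compound
    names, molecular-interaction features obtained by random walk with restart
    on a protein-protein interaction network followed by variance-thresholded
    principal component reduction, and chemical-property features built from
    typed physicochemical descriptor tables (Z-scoring plus one-hot encoding).
    A block-masked partially connected deep neural network is trained per
    disease on drug indication labels with a class-weighted binary
    cross-entropy loss, Adam optimisation and early stopping, and compared
    against five network-proximity baselines (closest, shortest, kernel,
    centre, separation). Includes a synthetic-fixture generator with a
    planted, recoverable compound-disease signal, evaluation utilities
    (splits, cross-validation, AUROC, accuracy) and a literature-statistics
    validation suite (co-occurrence, Jaccard index, Fisher's exact test,
    Mann-Whitney U).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
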