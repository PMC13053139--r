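Package: keystonet
Title: Activity-Informed Keystone Taxon Analysis for Paired Metagenome and
    Metatranscriptome Abundance Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Workflow for identifying putative keystone taxa in microbial
    communities from paired metagenomic (DNA) and metatranscriptomic (RNA)
    sample-by-taxon count matrices. Provides compositional normalisations
    (total-sum scaling, Hellinger, centered log-ratio, min-max), Bray-Curtis
    ordination and multi-factor PERMANOVA with pairwise contrasts, sparse
    co-occurrence network inference by graphical lasso with StARS stability
    selection and degree-centrality ranking, a penalised Gaussian chain graph
    linking taxa to environmental predictors, and a permutation-based
    connectivity robustness index that contrasts a focal taxon's network role
    across re-assembled communities in the abundance and expression layers.
    Includes a seeded synthetic-data generator with planted hub taxa,
    environmental effects and an expression layer whose network can be
    decoupled from the abundance layer, so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    vegan,
    glmnet,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
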