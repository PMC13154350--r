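Package: correnet
Title: Correlation Networks and Pseudomolecular Ion Identification for LC-MS Feature Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds interpretable weighted correlation networks from
    nontargeted LC-MS metabolomics feature tables. Features (adducts,
    fragments, isotopologues, dimers) originating from one metabolite are
    grouped into cliques by retention-time coincidence and stable
    cross-sample intensity ratios; each clique's pseudomolecular ion is
    identified by a weighted mass-difference voting scheme over a
    user-editable adduct/neutral-loss rule system; metabolite concentration
    profiles are correlated (Pearson, with optional Bonferroni correction),
    correlations are rescaled into layout weights, edges are thinned to one
    primary edge per node plus a one-third quota of opposite-sign edges, and
    the network is spatialized with a seeded stress-based force-directed
    layout scored by DBSCAN cluster count and mean silhouette. A synthetic
    feature-table generator with known ground truth supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'rules.R'
    'feature-io.R'
    'grouping.R'
    'pseudoion.R'
    'correlate.R'
    'network.R'
    'synth.R'
    'pipeline.R'
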