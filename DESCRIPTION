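Package: phyloilr
Title: Phylogenetic Isometric Log-Ratio Transform for Microbiome Compositions
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Transforms sample-by-taxon relative abundance tables into
    orthonormal balance coordinates using a rooted phylogeny as the
    sequential binary partition (the PhILR transform). Supports a
    generalized isometric log-ratio basis with per-taxon weights that
    soft-threshold zero-laden taxa, and branch-length weighting of
    balances. Includes preprocessing (zero replacement, count and sample
    filtering, table-tree reconciliation), balance-space Euclidean
    distances, a permutation test for the dependence of balance variance
    on phylogenetic depth, consensus taxonomy naming of balances, and a
    logistic-normal multinomial simulator with tunable phylogenetic
    covariance for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    MASS,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Phylogenetics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'analysis.R'
    'cli.R'
    'fixtures.R'
    'io.R'
    'methods.R'
    'phyloilr-package.R'
    'preprocess.R'
    'taxonomy.R'
    'transform.R'
    'tree.R'
    'weights.R'
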