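Package: lspplace
Title: Distance-Based Phylogenetic Placement with Statistical Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Places query sequences on a fixed backbone phylogeny by weighted
    least-squares fitting of corrected sequence distances (LSPP), and attaches
    statistical support to each placement. Support is estimated by fast
    (linear-algebraic) nonparametric bootstrapping, slow bootstrapping with
    branch-length re-estimation, m-out-of-n site subsampling with variance
    correction, or parametric binomial/Poisson resampling of distances.
    Includes JC69 and Scoredist distance estimators, a calibration / ROC /
    ECDF / top-k evaluation framework for support values, jplace v3 output,
    and a JC69 sequence simulator for generating test scenarios with known
    true placements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite,
    pracma,
    parallel
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alignment-io.R'
    'cli.R'
    'distances.R'
    'evaluation.R'
    'lspplace-package.R'
    'placement.R'
    'support.R'
    'synthetic.R'
    'tree-io.R'
    'utils.R'
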