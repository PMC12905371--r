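Package: leakSplit
Title: Leakage-Aware Train/Validation/Test Splitting for Molecular and
    Sequence Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Splits cheminformatics and protein-sequence datasets into
    train/validation/test partitions while minimizing information leakage
    between partitions, and scores the leakage of any given split with a
    scaled leakage score in [0,1]. Provides Needleman-Wunsch sequence
    identity and Morgan/ECFP fingerprint similarities (Tanimoto, Dice),
    single-linkage similarity clustering, an exact/heuristic cluster-to-split
    assignment solver for one- and two-dimensional (interaction) datasets,
    reference baseline splitters (random, stratified, Bemis-Murcko
    scaffold), degree-preserving negative sampling, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, Cheminformatics, Proteomics, Classification
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
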