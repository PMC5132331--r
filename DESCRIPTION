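Package: dnabindR
Title: Sequence-Based Prediction of DNA-Binding Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts DNA-binding proteins from sequence-derived features.
    Implements three feature encoders (a 120-dimensional projection of
    sigmoid-scaled PSI-BLAST profile columns onto physicochemical property
    axes, reliability-weighted binding/non-binding propensity measures
    computed from per-residue binding predictions, and 168
    composition/transition/distribution descriptors over eight three-group
    amino-acid partitions), minimum-redundancy maximum-relevance feature
    ranking with incremental feature selection, and a random-forest
    classifier evaluated by stratified five-fold cross-validation. A
    synthetic-data generator emulates all input streams with controllable
    class signal so the full pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
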