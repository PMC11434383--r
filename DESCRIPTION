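Package: piRNAdx
Title: Sequence-Descriptor Classification of Disease-Associated piRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic featurization of PIWI-interacting RNA (piRNA)
    sequences into a canonical panel of 1020 descriptors (nucleotide
    composition, mean base mass, hydrogen-bond capacity, mirror symmetry, and
    overlapping 2-/3-/4-mer motif counts over the whole sequence and over its
    first and last five nucleotides), information-gain descriptor ranking with
    Fayyad-Irani minimum-description-length discretization, a multinomial
    naive Bayes classifier implemented from first principles plus a pluggable
    contract for alternate classifiers, stratified cross-validation with the
    full confusion-matrix metric suite and ROC/PR curves, independent-set
    positive-rate evaluation, and a seeded synthetic-sequence generator with
    planted class-specific motifs so the whole pipeline is testable without
    external downloads. Includes the packaged piRNA identifier lists used to
    assemble colorectal-cancer training and validation panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    randomForest,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
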