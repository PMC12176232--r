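Package: protclass
Title: Protein Sequence Classification from Compositional Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns FASTA files of positive and negative protein sequences into
    trained binary classifiers. Provides three sequence-composition encoders
    (amino-acid composition, di-peptide composition, and Chou's pseudo
    amino-acid composition), CD-HIT-style greedy redundancy filtering,
    preprocessing (IQR outlier removal, point-biserial feature selection,
    jittered replica augmentation, stratified splitting), a registry of six
    classical classifier families, and confusion-matrix evaluation with
    accuracy, recall, specificity and F1. Includes a seeded synthetic-sequence
    generator with class-dependent compositional bias so the full pipeline is
    testable offline, and the reported benchmark tables of a chronic myeloid
    leukemia protein-sequence study for arithmetic cross-checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
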