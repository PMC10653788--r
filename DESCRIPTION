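Package: contamaudit
Title: Diagnostics for Host-Read Contamination and Normalization Leakage in
    Microbiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to diagnose two failure modes of large-scale
    cancer-microbiome analyses: inflation of taxonomic read counts caused by
    human reads matching human-contaminated draft genomes, and information
    leakage introduced when supervised normalization imprints class labels
    onto features whose raw counts are all zero. Provides seeded simulators
    for sparse overdispersed count matrices and contaminated toy genomes, a
    voom-style log-CPM transform with an explicitly supervised or blind
    SNM-style adjustment, an empty-submatrix one-vs-rest classifier audit,
    count-matrix comparison statistics, residual host-read accounting, and a
    minimal exact 31-mer lowest-common-ancestor read classifier.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    xgboost,
    pROC,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    glmnet
Config/testthat/edition: 3
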