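Package: antioxpred
Title: Antioxidant Protein Classification via Variational Feature Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies proteins as antioxidant or non-antioxidant from
    evolutionary and structural profiles. Extracts a 473-dimensional feature
    vector per sequence (PSSM column means, consensus-sequence n-gram
    composition, and secondary-structure composition, run-length, motif and
    probability features), rebalances the two classes with SMOTE minority
    oversampling, compresses the features to a 15-dimensional latent
    representation with a variational information-bottleneck encoder, and
    classifies the latent features with gradient-boosted trees. Includes
    readers for PSI-BLAST ASCII PSSM and PSI-PRED ss2 files, a synthetic-data
    generator for end-to-end testing, stratified k-fold cross-validation with
    confusion-matrix metrics, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
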