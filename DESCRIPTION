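Package: gdgse
Title: Gene Set Enrichment by Discretized Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample gene set enrichment scoring for bulk and
    single-cell transcriptomes based on discretized expression values.
    Each gene is binarized against reference-condition statistics (mean
    plus one standard deviation) and a gene set is scored per sample as
    the fraction of its member genes exceeding threshold. Includes a
    one-vs-rest mode for cell-type signature scoring, a permutation
    significance test with a label-permutation null-calibration harness,
    synthetic two-condition and single-cell data generators with planted
    gene-set activation and additive Gaussian noise, clustering
    evaluation metrics (adjusted Rand index, silhouette, balanced
    accuracy, coefficient of variation), and readers/writers for dense
    TSV/CSV, MatrixMarket and GMT formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods,
    Matrix,
    jsonlite,
    mclust,
    cluster
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
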