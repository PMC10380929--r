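Package: pinnet
Title: Pathway-Informed Neural Networks for Interpretable Transcriptomic
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a pathway-informed deep neural network (PINNet) for
    case/control classification from gene-expression matrices. A binary
    pathway-by-gene mask constrains the first hidden layer so that each
    pathway node only receives input from its member genes; a parallel fully
    connected branch captures relationships outside curated pathways. The
    package provides expression preprocessing (imputation, interquartile-range
    probe filtering, probe-to-gene collapse, min-max scaling), MSigDB GMT
    gene-set handling and mask construction, SMOTE class balancing, stratified
    10-fold cross-validation with grid search and early stopping, DeepLIFT
    rescale-rule (Deep SHAP) attribution for gene and pathway nodes with exact
    summation-to-delta, cross-fold importance scoring, known-gene enrichment
    tests, an importance-based feature-selection experiment, and a synthetic
    transcriptome generator with planted pathway-level differential signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
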