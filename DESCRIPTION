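Package: qsardpp
Title: QSAR Modeling of DPP-IV Inhibitory Activity with mRMR-BFS Feature
    Selection and Support Vector Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A quantitative structure-activity relationship (QSAR) toolkit
    for predicting the inhibitory activity (pIC50) of dipeptidyl peptidase IV
    (DPP-IV) inhibitors from physicochemical descriptors. Reads V2000 MOL/SDF
    structure files, computes elemental-analysis, topology and geometry
    descriptors, ranks features by the minimum-redundancy maximum-relevance
    (mRMR) criterion with discretized mutual information, performs
    backward feature elimination driven by leave-one-out cross-validated
    epsilon support vector regression (SVR) with a radial basis function
    kernel, and validates models with q-squared and RMSE statistics. Ships a
    48-compound pyrrolidine-amide benchmark fixture, a synthetic feature-table
    generator with planted signal for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
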