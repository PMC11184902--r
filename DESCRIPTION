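Package: dcca
Title: Differential Canonical Correlation Analysis for Paired Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects differential covariation patterns between two blocks of
    high-dimensional omics data (e.g. miRNA and gene expression) measured on
    the same samples across two clinical groups. Finds loading vectors that
    maximize the overall cross-block canonical correlation plus a tuning
    parameter times the absolute between-group difference of the group-wise
    canonical correlations, with the tuning parameter chosen by stratified
    cross-validation. For ultra-high-dimensional inputs, a bipartite
    quasi-biclique screening step extracts dense sub-blocks of the
    thresholded feature-feature correlation graph, with the biclique density
    exponent tuned by a Kullback-Leibler criterion under a Bernoulli-mixture
    model. Includes a Fisher-z test for the between-group difference of
    canonical correlations, classification diagnostics based on the canonical
    variables, and a simulation framework with block-sparse coefficient
    matrices for power and false-positive-rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    MASS,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
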