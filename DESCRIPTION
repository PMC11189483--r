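Package: nnice
Title: Deep Quantile Regression Deconvolution of Immune Cell Fractions from Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates immune cell-type fractions (and their uncertainty
    intervals) from bulk RNA-seq expression profiles by training one
    single-output dense quantile-regression network per (cell type,
    quantile) pair on pseudo-bulk mixtures simulated from a labeled
    single-cell reference. Includes a negative-binomial single-cell
    simulator, quality-control filtering of cells, variance-stabilized
    highly-variable-gene feature selection, Dirichlet pseudo-bulk mixing
    with known ground-truth fractions, the tilted (pinball) and composite
    correlation/RMSE training objectives, k-fold cross-validated
    evaluation, and tidy/ggplot2 reporting of the results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
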