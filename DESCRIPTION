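Package: lincsprofiler
Title: Distributional and Differential-Expression Profiling of LINCS
    L1000 Signature Compendia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing large perturbational gene-expression
    signature collections in the LINCS L1000 style. Reads and writes
    signature metadata (TSV) and landmark-gene z-score matrices (GCT 1.3
    text and GCTX HDF5), summarizes experimental-condition distributions
    (cell lines, perturbation categories, replicates, dosages, time
    points), counts differentially expressed genes by z-score
    thresholding, tabulates cumulative significance categories overall and
    stratified by cell line, dose group and time point, and computes
    change fractions between condition pairs with a parallel/intersecting
    segment classification. A synthetic LINCS-shaped data generator with
    planted differential-expression effects and exact analytic oracles
    makes the whole pipeline testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
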