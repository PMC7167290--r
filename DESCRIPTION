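Package: UbLsig
Title: Discovery and Scoring of Ubiquitin/SUMO Conjugation Signatures of
    AML Chemoresistance from Protein Arrays
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements an end-to-end pipeline for discovering a
    ubiquitin-family (UbL) conjugation signature of acute myeloid leukemia
    chemoresistance from two-channel protein-array experiments, and for
    scoring new samples as chemosensitive or chemoresistant. Includes a
    GenePix Results (GPR) reader, background correction, duplicate-spot
    averaging, within-experiment quantile normalization and
    cross-experiment batch adjustment, modification calling against
    NEM-treated control arrays using dual Welch and Wilcoxon-Mann-Whitney
    tests, differential-modification calling on resistant/parental ratios
    (global and per cell line x drug), signature merging, genetic-algorithm
    feature selection with selection-frequency ranking and nested subsets,
    linear discriminant scoring with cross-validation, and quantification
    of a multiplexed bead (xMAP-style) assay from event-level cytometry
    tables. A synthetic-data module generates protein-array scans and bead
    event tables with planted ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    MASS,
    sva,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, Normalization, Classification, CellBasedAssays
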