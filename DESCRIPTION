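Package: ddixome
Title: Transcriptome-Based Analysis of Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterising drug-drug interactions from bulk
    RNA-seq count data. Implements negative-binomial differential expression
    with TMM normalization (edgeR-approximating exact test), directional
    classification of shared differentially expressed genes into positive
    (synergistic) and negative (antagonistic) interaction classes, right-sided
    hypergeometric over-representation analysis with Benjamini-Hochberg
    correction and pathway-level directionality statistics, WGCNA-style
    co-expression module detection with module-trait correlation, and
    protein-interaction hub ranking for target nomination. Includes a fully
    specified synthetic-data generator with planted ground truth so every
    stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust
Config/testthat/edition: 3
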