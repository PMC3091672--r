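Package: sagexpr
Title: SuperSAGE Tag Extraction, Differential Expression, Annotation and
    Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of SuperSAGE (26-bp serial analysis of
    gene expression) libraries sequenced as ditags: demultiplexing and
    quality control of ditag reads, mono-tag extraction and tag counting,
    multi-library differential-expression calling by replicated G-tests and
    pairwise two-proportion Z-tests with zero-substitution fold changes,
    exact-match tag-to-DNA annotation with antisense transcript detection,
    chi-square-distance K-means clustering of expression profiles with
    Gap-statistic model selection, and gene-ontology enrichment against a
    control-library background.  A synthetic-data generator emulating
    five-library pufferfish gill experiments makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Clustering, Annotation, Sequencing
RoxygenNote: 7.3.3
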