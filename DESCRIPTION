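Package: lncmod
Title: Stage-Associated lncRNA Coexpression Modules and Hub Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery of tumor-stage-associated long noncoding RNA (lncRNA)
    coexpression modules and hub lncRNAs from microarray expression data.
    Provides microarray probe reannotation to lncRNA transcripts by exact
    sequence matching with perfect/specific/multi-probe filters, sample-network
    quality control with standardized connectivity and clustering-coefficient
    statistics, weighted coexpression network construction with scale-free
    soft-threshold selection and topological overlap modules, module eigengene
    and module significance screening against an ordinal stage trait, dual
    correlation hub selection, one-way ANOVA stage trends, hypergeometric
    gene-set over-representation with Benjamini-Hochberg control, and
    Kaplan-Meier/log-rank survival comparisons. A synthetic-data generator
    plants coexpression modules, stage effects, hub genes, probe universes
    with decoys, and survival effects so every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    S4Vectors,
    limma,
    survival,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
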