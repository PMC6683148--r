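Package: seedmir
Title: Small RNA-Seq miRNA Discovery and Expression Profiling in Conifer Seed Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable small-RNA transcriptome pipeline for conifer seed
    tissues (zygotic embryos, somatic embryos and megagametophytes): read
    collapsing and length/abundance/contaminant filtering, exact genome
    mapping, conserved miRNA annotation against a mature reference with up
    to two mismatches, novel miRNA prediction from genomic hairpin
    precursors with miRNA-star detection and high-confidence calls, CPM
    normalization, correlation-matrix PCA, ANOVA/t-test differential
    expression and expression-profile clustering, plant-style miRNA target
    prediction with an expectation score, and hypergeometric GO-term
    enrichment with Benjamini-Hochberg correction. A synthetic-data module
    generates a toy genome with planted hairpins, siRNA loci and
    contaminants plus simulated libraries with full ground truth, so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    data.table,
    cluster,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
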