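Package: cernet
Title: Competing Endogenous RNA Network Inference for Two-Condition
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for lncRNA-miRNA-mRNA competing
    endogenous RNA (ceRNA) network inference from bulk two-condition
    transcriptomes, modelled on hair-follicle anagen/catagen skin
    comparisons. Provides a five-criterion novel-lncRNA identification
    cascade with pluggable coding-potential predictors, two-group
    differential expression with Benjamini-Hochberg FDR control, lncRNA
    target prediction in cis (genomic windows) and in trans (Pearson
    co-expression with significance and FDR screening), canonical miRNA
    seed-site prediction (8mer, 7mer-m8, 7mer-A1, 6mer), shared
    miRNA-response-element detection, direction-concordant ceRNA triad
    assembly with SIF/GraphML export, hypergeometric over-representation
    analysis, and a fully self-contained synthetic data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
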