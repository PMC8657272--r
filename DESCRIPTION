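Package: miris
Title: Integrated miRNA-mRNA Interaction Scoring for Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Maintainer", "miris", email = "miris@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that integrates small RNA-seq differential
    expression, multi-source miRNA target predictions, meta-3'-UTR binding
    site mapping, CRISPR essentiality screens and survival evidence into a
    per-interaction Interaction Score (IS) and a gene-level OncoScore (OS).
    Implements TMM normalization, a negative-binomial exact test with
    Benjamini-Hochberg FDR control, Kaplan-Meier/log-rank hazard ratio
    screening by median expression split, unweighted pre-ranked gene set
    enrichment, signature extraction and unsupervised reporting utilities,
    together with a fully seeded synthetic cohort generator with a planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
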