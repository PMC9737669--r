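Package: seedLncRNA
Title: Identification and Regulatory Network Analysis of lncRNAs in Seed
    Aging RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a bulk strand-specific RNA-seq
    analysis of rice seed aging: long non-coding RNA identification by a
    five-round filter cascade (strand certainty, exon count, length,
    annotation overlap, expression, coding potential), lincRNA/lncNAT
    classification, negative-binomial differential expression between aged
    and fresh seeds, cis (genomic co-localization) and trans (expression
    correlation) target prediction, miRNA target scanning with plant-style
    scoring, ceRNA (lncRNA-miRNA-mRNA) network assembly, and hypergeometric
    term enrichment with rich factors. Ships a deterministic synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cascade.R'
    'cerna.R'
    'diffexpr.R'
    'enrich.R'
    'io.R'
    'orf.R'
    'pipeline.R'
    'synthetic.R'
    'targets.R'
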