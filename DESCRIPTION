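Package: rddmr
Title: Windowed DMR Calling and Classification of RdDM- and
    MORC-Dependent Silencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Whole-genome methylome, transcriptome and small-RNA analysis
    for plant silencing pathways. Calls differentially methylated regions
    (DMRs) from per-cytosine bisulfite counts with a fixed 50-bp window
    Fisher exact test, merges proximal windows into regions, partitions
    DMR sets between genotypes with a strict base-pair overlap rule and
    hypergeometric enrichment, computes feature-level and promoter
    methylation with context-specific class filters, applies a
    fold-change plus Fisher exact differential-expression rule, and
    profiles 24-nt siRNA abundance in reads per ten million (RPTM) to
    classify Pol IV / Pol V dependence. Includes a seeded synthetic-data
    generator with planted ground truth and an end-to-end pipeline with
    recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
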