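Package: h3varscan
Title: Genome-Wide Histone H3 Variant Deposition Analysis from ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for mapping where histone H3 variants
    (replication-coupled H3.1 versus replacement H3.3) are deposited along a
    genome, from aligned single-end ChIP-seq reads. Implements duplicate-read
    collapsing, a Poisson-background island caller for broad enrichment
    domains scored against a mock (Col-0) control, control-normalized
    metagene profiles over gene bodies and 2 kb flanks stratified by
    expression quintiles, peak-gene association and shared/unique peak
    grouping, H3-normalized histone-mark enrichment over peaks and genes,
    chromatin-state and housekeeping-gene enrichment summaries, and a
    diagnostic-residue classifier that calls H3 protein sequences as
    H3.1-like or H3.3-like (plant positions 31/41/87/90, animal
    31/87/89/90). Ships a synthetic-data module that plants known deposition
    archetypes (silent-region-enriched, expression-correlated with 3' bias,
    mixed, uniform control) in a miniature genome so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
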