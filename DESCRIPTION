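Package: fostarget
Title: Direct Transcription-Factor Target Discovery by Chromatin-State
    Gating and Single-Cell Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies candidate direct transcriptional targets of a
    transcription factor (c-Fos in rod photoreceptors, by default) by
    combining CUT&Tag peak calls for the factor and for the histone marks
    H3K27ac, H3K4me3 and H3K27me3 into an active-promoter gate around
    transcription start sites, intersecting condition-exclusive gated gene
    sets with condition-exclusive differentially expressed genes from a
    TF-positive versus TF-negative single-cell comparison, and dissecting
    candidate promoters with an AP-1/TRE motif scanner and a
    deletion-construct essential-region engine. Ships a seeded synthetic
    multi-omic generator (annotation, peaks, counts, promoter sequences,
    truth ledger) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
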