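Package: peakstates
Title: Chromatin-State Classification, Motif Enrichment and Expression
    Linkage for ChIP-Seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies genomic loci into regulatory chromatin states
    (active and poised promoters and enhancers, closed chromatin, other)
    from histone-mark ChIP-seq peak sets, and relates transcription-factor
    peak sets and their joint regions to those states and to RNA
    polymerase II occupancy. Scans summit-centered peak windows on both
    strands for position-weight-matrix motifs, computing the exact null
    score distribution by dynamic programming so that the bit-score cutoff
    controls a stated per-window false-positive rate, and tests motif
    enrichment against matched random background regions with one-sided
    Fisher and two-proportion z tests. Links peaks to transcription by
    counting RNA reads in summit-centered windows normalized per kilobase,
    restricted to promoter-proximal peaks. A seeded synthetic-data
    generator plants chromatin states, motif occurrences and read rates
    with a machine-readable truth file, so every stage has a
    parameter-recovery test that needs no external download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
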