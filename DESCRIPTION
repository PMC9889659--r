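Package: methtiler
Title: Tiling-Window Methylome Analysis for Two-Stage Fungal Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative whole-genome 5-methylcytosine analysis between two
    developmental stages of a fungus, built around per-site methylation
    frequency tables such as those produced by nanopore methylation callers.
    Classifies every genomic cytosine into CG/CHG/CHH context on both strands,
    computes global and windowed methylation levels, metagene profiles around
    transcription start/end sites and across transposable-element bodies,
    calls differentially methylated regions (DMRs) with a non-overlapping
    tiling-window Fisher's exact test, assigns DMRs to genomic compartments,
    derives promoter-overlap differentially methylated genes, scores
    transposable-element enrichment, and tests GO-term over-representation.
    Includes a seeded synthetic-methylome generator with planted DMRs that
    provides ground truth for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
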