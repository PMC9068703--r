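Package: regulonscout
Title: Regulon Inference for Uncharacterized LysR-Type Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates four evidence streams to propose regulons for
    poorly characterized bacterial LysR-type transcription factors:
    phylogenetic footprinting of orthologous promoter regions for
    palindromic binding-site discovery, ChIP-exo peak-to-target
    assignment, conserved gene-neighborhood analysis across related
    genomes, and differential expression in regulator-knockout strains.
    Produces a scored per-target evidence table with activator/repressor
    mode calls, and ships a synthetic-data generator that emulates the
    statistical structure of each input so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
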