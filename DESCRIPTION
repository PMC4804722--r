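Package: tfbsnet
Title: Stage-Specific Transcription Factor Binding Site Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects co-occurring transcription factor binding site (TFBS) pairs
    in promoter sets of stage-specific differentially expressed genes, builds
    frequency-weighted TFBS co-occurrence networks per developmental stage,
    clusters them with the Markov clustering algorithm (MCL), and tracks
    hub-centered clusters across stages with temporal-pattern classification,
    expression-threshold annotation of the underlying transcription factor
    genes, and an hourglass profile of per-stage counts. Includes a seeded
    synthetic-data generator emulating a six-timepoint FPKM expression time
    course with planted composite binding-site pairs, so that every pipeline
    step has a ground-truth oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
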