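Package: retrotag
Title: Detection and Characterization of Somatic LINE-1 3' Transductions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing somatic LINE-1 (L1)
    3' transductions in cancer genomes. Implements tag-based detection of
    transduction-supporting read pairs in short-read alignments, annotation
    of reconstructed long-read insertion sequences (class, source assignment,
    component lengths, 5' inversions, proxy and multigenerational cascade
    resolution), retrotransposition hallmark scoring (target site
    duplication, polyA tail, endonuclease cut site), polyadenylation-signal
    scanning with a position weight matrix, rectangular-kernel clustering of
    inversion breakpoints, and promoter CpG methylation association with
    source-element activity. A seeded synthetic-data generator produces a
    complete miniature study (reference genome with planted source L1s,
    insertion truth sets, analytically aligned paired-end reads,
    reconstructed insertion sequences and per-CpG methylation tables) so
    that every stage is verifiable without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
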