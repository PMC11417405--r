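Package: corec
Title: Cofactor Recruitment Motif Analysis from Protein-Binding Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cofactor recruitment (CoRec) protein-binding
    microarray experiments. Builds consensus + single-variant probe designs
    from reference motif libraries, converts probe-level fluorescence into
    background-normalised recruitment z-scores, derives delta-z recruitment
    motifs with adaptive-beta Boltzmann probability matrices and motif
    strength scores, matches recruitment motifs to reference motif libraries
    with Monte-Carlo significance, builds transcription-factor motif
    clusters, assembles cofactor-by-condition recruitment networks, and
    relates motif content of promoters to histone-acetylation levels via
    exact-p-value position-weight-matrix scanning. Includes a synthetic-data
    generator so the full pipeline can be exercised and validated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
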