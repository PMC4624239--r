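Package: crescan
Title: Permutation-Tolerant Enhancer Similarity Scanning
Version: 0.1.0
Authors@R:
    person("crescan", "developers", email = "crescan@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate cis-regulatory elements (enhancers) in a
    target genome from a single query enhancer sequence, with no training
    data or multi-species alignments.  A seed-and-extend step builds a
    mismatch-tolerant motif profile between query and target, windows are
    scored by the summed motif scores (tolerating motif permutation), a
    co-linear pattern detector rewards conserved motif arrangements, and
    candidate regions are called with a median + 3*MAD threshold.  Includes
    candidate-assessment utilities (orthologous-flank classification,
    random motif sets, conservation-score comparison) and a synthetic
    sequence-evolution simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
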