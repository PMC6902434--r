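Package: jctsig
Title: Breakpoint Junction Signature Analysis for Copy-Number Gain
    Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and classification of microhomology and
    microhomeology at structural-variant breakpoint junctions,
    substrate-similarity profiling around join-points with an anchored
    Needleman-Wunsch alignment and a 20-bp moving-window identity score,
    and classification of per-individual copy-number profiles into
    rearrangement patterns (single duplication, DUP-NML-DUP, DUP-TRP-DUP
    and other complex genomic rearrangements) with cohort frequency
    summaries. Includes a seeded simulator of references, junctions with
    planted join-point signatures, and multi-segment rearrangement
    structures with truth tables, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    grDevices,
    graphics,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
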