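Package: motifstems
Title: Motif Stem Search for Planted (l,d)-Motifs on Large Alphabets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact search for motif stems -- fixed-length patterns with
    wildcard positions that together cover every planted (l,d)-motif in a
    set of DNA or protein sequences. Implements two stem-search drivers
    (one with per-candidate neighbour scans, one built on an O(1)
    per-cell diagonal recurrence for the pairwise l-mer distance matrix),
    the pairwise-stemming baseline they improve on, a brute-force
    planted-motif oracle for validation, closed-form neighbourhood
    probabilities with challenging-instance computation, and a seeded
    generator of synthetic planted-motif benchmark instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
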