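Package: cambscan
Title: Calmodulin-Binding Domain and Motif Scanning for Neuroinflammation Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies putative calmodulin-binding domains (CaMBDs) and
    enumerates calcium-dependent anchor-spacing motifs (1-10, 1-12, 1-14,
    1-16, 1-5-10, 1-5-8-14) and calcium-independent IQ-family motifs in
    protein sequences.  Ships a curated corpus of thirteen CaMBDs reported
    across eleven neuroinflammation-linked proteins (ABCA7, CD33, CH3L1,
    CLU, CR1, EPHA1, MS4A4E, MS4A6A, NLRP3, PILRA, TREM2) together with
    their reported per-class motif counts, and provides a concordance
    report comparing reported counts against systematic enumeration.
    Includes a heuristic basic-amphipathic-helix domain caller, a seeded
    synthetic-data generator for planted-motif benchmarking, and tabular
    (TSV/JSON) report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
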