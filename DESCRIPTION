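Package: crsscan
Title: Scanning Germline VH Genes for the 3' Cryptic Recombination Signal
    Sequence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies the heptamer of the 3' cryptic
    recombination signal sequence (3'cRSS) embedded at codons 103-105 of
    germline immunoglobulin heavy-chain variable (VH) genes, anchored at the
    conserved 2nd-CYS (Cys104, IMGT unique numbering). Extracts the
    downstream VH-replacement footprint, translates it in three reading
    frames and scores charged amino-acid content against the 14/64 random
    baseline, runs the parallel best-frame analysis on germline DH genes,
    and aggregates heptamer-class frequencies by family, species and
    cross-species clade group, with an optional deterministic
    neighbor-joining guide tree on framework-region alignments. Ships a
    seeded synthetic repertoire generator with a ground-truth ledger so the
    whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
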