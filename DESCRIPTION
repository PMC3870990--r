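Package: srnamine
Title: Small RNA Transcriptome Mining: miRNA Quantification, Differential
    Expression and Novel Hairpin Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis toolkit: contaminant
    filtering, mature miRNA matching with family-aware multi-hit collapsing,
    max-normalized two-fold differential expression calls, and a novel miRNA
    candidate discovery branch (abundant unmatched reads, exact genome mapping,
    positional clustering, +/-100 nt precursor extension, hairpin folding with a
    pair-scored Nussinov dynamic program, read-in-stem classification, seeded
    similarity search against a curated ncRNA database, false-positive
    exclusion, external structural/ab-initio evidence adapters, adjacent
    candidate merging and tiered evidence integration). Includes a synthetic
    data generator that plants known miRNA hairpins, novel hairpins,
    contaminants and decoys in a toy genome with per-locus expression and a
    ground-truth table, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
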