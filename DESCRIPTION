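Package: cladebar
Title: Clade-Specific Diagnostic DNA Barcodes from Plastome Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing character-based DNA barcodes that identify
    clades (Operational Phylogenetic Units, OPUs) rather than individual
    species, for groups where species are polyphyletic and a barcoding gap is
    absent. Starting from a whole-plastome multiple sequence alignment,
    columns are classified as variable or parsimony-informative, SNP density
    is summarised in fixed windows, candidate barcode regions are selected
    under variability and masking thresholds, merged, and refined with
    sub-windows. Barcode regions are scored (length, variable and
    parsimony-informative sites), sequences are collapsed into haplotypes
    with per-group sharing summaries, clade-diagnostic nucleotide positions
    are extracted into a diagnostic matrix, minimal diagnostic position sets
    are searched exhaustively or greedily, and query samples (for example
    commercial herbal products) are classified against the matrix with
    missing-data tolerance. A seeded simulator generates alignments with
    controlled counts of variable, parsimony-informative and planted
    clade-diagnostic columns for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
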