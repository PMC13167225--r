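Package: coicurate
Title: Curation and Validation of COI-5P DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building, quality-filtering and validating DNA barcode
    reference libraries based on the COI-5P marker. Implements the standard
    curation workflow for BOLD-style datasets: length-window and stop-codon
    filtering under the invertebrate mitochondrial genetic code, haplotype
    richness per species, uncorrected pairwise distances with pairwise
    deletion, barcode-gap statistics (maximum intraspecific distance and
    minimum nearest-neighbor distance) with distance-anomaly flagging,
    tree-based species monophyly assessment with intruder reports supporting
    a two-pass curation loop, and BIN concordance accounting. A synthetic
    library generator with injectable error processes (misidentification,
    contamination, NUMTs, sub-length and ambiguous sequences, barcode
    sharing) provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    graphics,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
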