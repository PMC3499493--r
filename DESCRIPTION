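Package: barcodeGap
Title: DNA Barcode Species Delineation via the Barcoding-Gap Threshold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A distance-based species delineation pipeline for COI DNA
    barcodes. Reads labelled barcode alignments, applies sequence quality
    control (length and reading-frame checks under the vertebrate
    mitochondrial code), computes pairwise Kimura 2-parameter distances with
    pairwise deletion, builds neighbor-joining trees with column-bootstrap
    clade supports, partitions distances into conspecific and congeneric
    sets, derives the maximum-conspecific / minimum-congeneric thresholds
    and their fold-ratio barcoding gap, flags mislabelled and
    deep-divergent records, classifies reference-database similarity
    matches into significance bands and ambiguity categories, and ships a
    Kimura 2-parameter sequence simulator with truth tables for validating
    the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
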