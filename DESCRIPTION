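Package: gefseq
Title: Base-Pair-Resolution Genome Footprinting Analysis for DNase
    I-Protected Fragment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects base-pair-resolution protein-protected regions
    ("components") from DNase I-digested paired-end fragment data of the
    GeF-seq type: fragment-end pileup profiling, calling of 70-110 bp
    protected regions above a library-size-scaled depth threshold,
    grouping of overlapping components into peaks, cross-condition
    occupancy comparison with normalized read numbers and
    timepoint-specificity labels, and IUPAC degenerate consensus
    scanning of called regions.  Includes a synthetic-data generator
    that emulates adapter read-through paired-end sequencing of short
    protected fragments, and read preparation (adapter-boundary
    trimming and exact-match fragment placement) to recover fragment
    intervals from reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
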