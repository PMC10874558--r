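Package: knockinr
Title: Classification of On-Target Knock-In Insertion Patterns from
    Nanopore Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes CRISPR knock-in outcomes at a cut site from
    barcoded long-read amplicon sequencing. Demultiplexes pooled nanopore
    reads with indel-tolerant 11-mer barcode probes, bins reads by expected
    product length, calls per-read insertion patterns (which donor fragments,
    how many copies, which orientation) with exact 17-mer probe sets,
    classifies correctly oriented donor insertions as NHEJ or HDR by
    homology-arm copy number, detects degraded donor pieces and foreign
    inserts (editing-plasmid remnants, endogenous genomic fragments, LINE-1),
    and computes deletion metrics (deletion index, D100) and length
    distributions. Includes a synthetic read simulator with full per-read
    ground truth so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    S4Vectors,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
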