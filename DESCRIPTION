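Package: taxokit
Title: Post-Processing Toolkit for Metagenomic Taxonomic Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless data layer for interactive taxonomic-profiling
    applications. Reads, validates and bit-faithfully rewrites Kraken-format
    taxonomy reports; converts them into a layered Sankey graph with
    threshold/top-N filtering, subtree re-rooting and round-trip validation
    back to the report; extracts reads classified under a taxon or its
    descendants from FASTA/FASTQ files by classification line number; merges
    sorted k-mer lists with species-level deduplication for incremental
    database updates; and assembles co-linear k-mer match chains with a
    single-pass algorithm verified against a graph-and-DFS reference.
    Deterministic synthetic-data generators make every component testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
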