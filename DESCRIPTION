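Package: lociscan
Title: Degenerate Consensus Matrix Scanning of miRNA Genomic Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide scanning of user-defined degenerate DNA consensus
    matrices (such as the NF-Y CCAAT-box matrix D/V/V/C/C/A/A/T/S/N/V) across
    miRNA-anchored genomic windows. Builds a flat-file locus database from a
    genome FASTA and miRBase/miRStart-style annotation, extracts strand-aware
    windows around pre-miRNAs, and finds all matrix occurrences on both strands
    with a brute-force matcher or an anchored Boyer-Moore matcher, under
    configurable mismatch policies (invariant core plus flanking-identity
    threshold). Hits are reported relative to the pre-miRNA or its
    transcription start site, with region-restricted searches, summary tables,
    hit-count and positional histograms, TSV/CSV export, a planted-motif
    synthetic data generator with exact ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    optparse,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
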