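Package: mirsieve
Title: Adaptive Thresholding and Profiling of Small RNA-Seq miRNA Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy workflow for deep-sequencing small-RNA libraries: collapse
    reads into unique-tag count tables, map tags to a mature-miRNA reference
    with bounded mismatches, project counts onto genomic peak tracks, select a
    data-driven minimum count threshold by an iterative two-sample
    Kolmogorov-Smirnov sweep across biological replicates, partition miRNAs
    into abundance tiers with kappa-quantified replicate agreement, rank
    miRNAs and compare top lists, and sieve gene-interaction networks for
    common hub nodes with housekeeping-normalised expression ratios. Includes
    generators for synthetic reads, count mixtures, networks and expression
    matrices so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
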