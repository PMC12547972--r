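Package: splithom
Title: Full-Length and Split Homolog Detection Between a Host Proteome and a
    Gut Microbial Protein Catalog
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gut microbial homologs of host proteins from protein-protein
    alignment tables, including "split" homologs encoded by multiple adjacent
    genes on one microbial contig that jointly, but not individually, cover a
    host protein. Implements coverage filtering, a percent-identity
    contamination cutoff, gene-neighborhood adjacency analysis, per-protein
    homolog tallies with a coverage-threshold sensitivity grid, xenobiotic
    enzyme class partitioning with Faith's phylogenetic diversity, GO term
    enrichment with evidence-code subsets, and cross-referencing against a
    pharmacogenomics reaction table. Ships a deterministic synthetic fixture
    generator with planted ground truth so the whole pipeline is testable
    offline, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    readr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    phangorn,
    picante,
    igraph,
    IRanges,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
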