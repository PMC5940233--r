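Package: plastome
Title: Comparative Plastid Genome Gene-Content Analysis for Habitat Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastid genomes with a
    focus on habitat-linked gene retention and loss in red algae. Parses GenBank
    flat files into normalized gene inventories and genome summary statistics,
    assembles species-by-gene presence/absence matrices joined to habitat
    metadata, screens every gene for habitat association with concordance rates
    and chi-square tests, maps gene loss onto a rooted phylogeny by Fitch
    parsimony, classifies heme-oxygenase isotypes (HMOX1, HMOX2, pbsA) from
    hydropathy-based transmembrane segments and an N-terminal transit-peptide
    heuristic, and builds thresholded protein-similarity networks from BLAST
    tabular hit files. A synthetic-data generator (trees, habitat evolution,
    habitat-dependent gene loss, toy GenBank records, planted-architecture
    proteins, toy hit tables) makes every stage testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
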