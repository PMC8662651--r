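Package: kinclust
Title: Constraint-Based Hierarchical Classification of Protein Kinase Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers cluster-specific sequence constraints from a profile
    multiple sequence alignment of protein kinase domains, organises them
    into a nested cluster hierarchy, and scores and classifies sequences
    against that hierarchy with an "unclassified" sink. Downstream analyses
    cover all-versus-all cluster similarity, comparative sequence logos,
    taxonomic conservation against NCBI-taxdump-style taxonomies, intron
    phase and shared-intron mapping from exon length tables, and
    alphaD-alphaE kinase-insert loop length analysis. A synthetic-data
    generator with planted ground truth (constraint motifs, taxon
    emergence points, shared introns, insert length distributions) makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
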