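Package: rrnsplit
Title: Intragenomic 16S rRNA Variation and the Splitting of Genomes by ASVs and OTUs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how intragenomic variation among the 16S rRNA gene
    copies of a bacterial genome causes exact amplicon sequence variants
    (ASVs) to split single genomes into multiple units, and how the distance
    threshold used for de novo OTU clustering trades that splitting against
    the lumping of multiple species into one OTU. Provides an rrnDB-style
    genome catalog reader, hypervariable-region extraction against an
    E. coli reference, ASV dereplication, gap-policy-aware pairwise
    distances, an MCC-maximizing iterative OTU clusterer with furthest-
    neighbor and exhaustive oracles, species-controlled resampling
    statistics, and a seeded synthetic multi-copy-genome community
    generator so the whole pipeline runs without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
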