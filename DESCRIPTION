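Package: hetmotif
Title: Colored Network Motif Analysis of Drug-Disease-Gene Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an integrated, undirected drug-disease-gene association
    network from literature-derived subject-predicate-object records, finds
    statistically over-represented colored three-node subgraph patterns
    (network motifs) against a type-preserving degree-conserving randomized
    null model, aggregates the matches of significant motifs into a core
    network, and provides neighborhood analytics for disease-gene
    prioritization, disease-relationship inference and drug repositioning.
    Includes a fully seed-deterministic synthetic data generator emulating
    redundant literature predication streams with planted motifs, so every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    igraph,
    Matrix,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
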