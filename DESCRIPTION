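Package: dtcombo
Title: Network-Based Drug-Target Prediction and Multi-Pathway Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions on a bipartite network with the
    DT-Hybrid similarity-weighted resource-transfer recommender, scores each
    drug's predicted targets against its validated targets through a Gene
    Ontology node-distance similarity and a hypergeometric subset p-value, and
    finds near-minimal druggable target sets reaching a user gene list across
    a merged multi-pathway network via a bounded shortest-path index and
    Chvatal greedy set cover. All inputs are plain tab-separated files; seeded
    generators produce synthetic networks, ontologies and pathway fixtures so
    every pipeline runs without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
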