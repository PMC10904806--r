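Package: phylorisk
Title: Threatened Evolutionary History, EDGE2 Scores and Evolutionarily
    Distinct Lineages from Phylogenies and Red List Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the expected loss of phylogenetic diversity under
    IUCN Red List derived extinction probabilities, computes per-species
    EDGE2 prioritisation scores (terminal branch length, ED2, EDGE2) across
    distributions of replicate trees, imputes species missing from a
    phylogeny along branches of their genus, assesses families as
    evolutionarily distinct lineages (fully-threatened and EDGE Lineage
    criteria, stem ages, matched resampling nulls for population trends),
    and simulates synthetic clades with monophyletic genera and families so
    the whole pipeline runs end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
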