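Package: reefscape
Title: Seascape Genomics and Connectivity Indices for Coral Reef Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for seascape genomics of reef-building
    corals. Computes multi-statistic environmental descriptors (including a
    degree-heating bleaching alert frequency) from gridded marine series,
    fits per-genotype logistic genotype-environment association models with
    G and Wald scores and Storey q-value correction, estimates Weir-Cockerham
    pairwise FST, derives asymmetric least-cost sea distances from daily
    current fields, fits a linear FST-by-sea-distance connectivity model, and
    combines the two axes into per-reef conservation indices: outbound and
    inbound connectivity (OCI, ICI) and an adaptive potential index (API).
    Ships a synthetic seascape generator with planted adaptive signal and
    isolation-by-sea-distance so every stage can be validated against a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    geosphere,
    jsonlite,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
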