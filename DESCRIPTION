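Package: herbnet
Title: Network Proximity Inference for Herb-Ingredient-Target-Disease Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores herb-herb, ingredient-ingredient, herb-disease and
    ingredient-disease interactions by network proximity on a protein-protein
    interactome. Implements the closest, shortest, center and disease-directed
    distance metrics, three significance regimes (random-pair nulls with a
    one-tailed Fisher Z-test, per-test disease nulls, and an empirical 5%-tail
    threshold over formula co-occurrence pools), batch repositioning screens
    with stratified distance reports, five combination-recommendation query
    patterns with Louvain disease-module extraction, ADMET-based candidate
    filtering, and a synthetic-scenario generator with planted disease modules
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
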