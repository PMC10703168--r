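Package: microgsm
Title: Taxonomy-Aware Grouping-Scoring-Modeling Classification of Microbiome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies disease versus control samples from species-level
    metagenomic relative-abundance profiles using a Grouping-Scoring-Modeling
    (G-S-M) strategy. Species are grouped under a chosen taxonomic rank (genus,
    family, or order), each group is scored by internal cross-validated random
    forest accuracy on training data, cumulative top-k models are evaluated under
    Monte Carlo cross-validation, and per-iteration group rankings are aggregated
    into order-statistic significance values that are propagated to member
    species. Includes a reader for MetaPhlAn-style merged abundance tables and a
    taxonomy-structured compositional data simulator with controllable
    group-level class signal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
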