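Package: reactocap
Title: Amplicon Community Analysis and Predicted Metabolic Reaction Capacity
Version: 0.1.0
Authors@R: person("Reactocap", "Developers", role = c("aut", "cre"),
    email = "maintainers@reactocap.dev")
Description: Downstream analysis of 16S rRNA amplicon sequence variant (ASV)
    tables: filtering, relative abundance and taxonomic aggregation, core
    microbiota and compartment-overlap analysis, alpha and beta diversity
    (Jaccard, unweighted UniFrac, Aitchison, PhILR) with PERMANOVA and
    PERMDISP permutation tests, and prediction of community-level metabolic
    reaction abundances from collections of genome-scale metabolic models
    (GSMMs), with per-reaction differential testing and direction-aware
    subsystem enrichment. Includes a seeded synthetic-data generator with
    planted group effects so the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
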