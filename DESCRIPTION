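Package: soilassembly
Title: Community Assembly, Cross-Kingdom Networks and Biogeography of Soil Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline linking soil fungi and cross-kingdom species
    associations to bacterial biogeography and community assembly. Provides
    count-table handling (rarefaction, Shannon diversity, richness,
    Bray-Curtis dissimilarity, prevalence filtering), Spearman co-occurrence
    networks with per-sample subnetwork features and niche-preference
    statistics, beta-MNTD/beta-NTI null-model partitioning of deterministic
    versus stochastic assembly, distance-decay regressions, and
    driver-attribution statistics (Mantel and partial Mantel permutation
    tests, LMG variance decomposition, forward-selected distance-based
    ordination, random-forest importance with permutation significance).
    A synthetic-data generator plants known assembly regimes (neutral,
    homogeneous and variable selection, fungal-richness-coupled selection)
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
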