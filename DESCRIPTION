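Package: coremicro
Title: Core Microbiome Detection Across Heterogeneous 16S rRNA Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated meta-analysis of multi-study 16S rRNA
    amplicon count data, centred on detection of a core microbiome. Implements
    count-level sample and feature filters, four normalisation strategies
    (rarefaction, total-sum scaling, rarefied relative abundance, and centred
    log-ratio with multiplicative zero replacement), alpha diversity,
    Bray-Curtis, Euclidean and weighted UniFrac beta diversity with principal
    coordinate analysis, study-adjusted PERMANOVA with exact and restricted
    permutation modes, three core-microbiome definitions (abundance-occupancy
    thresholds and ranked occupancy-contribution prioritisation under two beta
    diversity metrics) with consensus, Spearman co-occurrence networks with hub
    detection, random-forest host-factor association with cross-validated
    feature selection, rank-sum differential abundance, sequence-identity
    affiliation of denoised variants to core taxa for independent-cohort
    validation, and a synthetic multi-study data generator with planted ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    biomformat,
    igraph,
    pROC,
    randomForest,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
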