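Package: coresweep
Title: Prevalence-Threshold Sensitivity of Core Microbiome Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how prevalence filtering used to define
    "core" gut microbiomes distorts diversity estimates. Implements four
    alpha diversity measures (observed richness, Shannon, Faith's
    phylogenetic diversity, balance-weighted phylogenetic diversity) and
    four beta dissimilarities (Jaccard, Morisita, unweighted and weighted
    UniFrac) over a shared edge-mass tree kernel; macroecological
    diagnostics (rarefaction, sample accumulation, jackknife-1 richness
    extrapolation, occupancy-abundance and rank-abundance curves); a
    prevalence-threshold sweep with per-species standardization, Bartlett
    variance profiles and filtered-versus-unfiltered Spearman
    correlations; and a seeded synthetic ASV-table generator with a
    lognormal metacommunity and negative-binomial sampling whose presets
    emulate published host gut microbiome datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    phyloseq,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
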