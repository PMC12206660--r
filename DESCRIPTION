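Package: coralscape
Title: Seascape Genomics of Coral Metapopulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An inference pipeline for seascape genomics of reef corals:
    identity-by-state genetic distances from per-allele read counts, cryptic
    lineage delineation by hierarchical clustering with cophenetic, silhouette
    and Mantel criteria, clone and sibling pruning, environmental raster
    construction from monitoring-station time series by Gaussian-kernel
    smoothing and ordinary kriging, multicollinearity pruning, random-forest
    genotype-environment association on genetic principal coordinates with
    jackknifed mtry-based predictor selection and turnover curves, and
    seascape-wide maps of adaptive neighborhoods, genetic offset between time
    slices, and environmental mismatch for transplantation planning. Includes
    a synthetic-data module generating coral metapopulations with planted
    lineage structure, depth niches, environmental clines, isolation by
    distance and clones, used as the test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    vegan,
    cluster,
    ranger,
    vcfR,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
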