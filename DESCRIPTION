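Package: seagrassGEA
Title: Genotype-Environment Association Scans and Climate-Adjusted
    Provenancing for Seagrass Meadows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for landscape-genomic analysis of estuarine
    seagrass meadows: SNP quality-control filtering of reduced-representation
    genotype data, replicate-based error estimation, nearest-neighbour
    imputation, compilation and collinearity pruning of environmental
    predictors, sparse non-negative matrix factorisation of ancestry with
    cross-entropy selection of K, and three genome scans for
    environment-associated loci (redundancy-analysis loading outliers, a
    principal-component Mahalanobis scan, and a latent-factor ridge
    regression scan) combined by a two-of-three consensus. Candidate loci
    feed a gradient-forest model of allelic turnover along environmental
    gradients, per-meadow zygosity mapping, and a climate-projection donor
    registry that matches meadows pre-adapted to projected future
    conditions. Includes a synthetic-data generator with known truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    methods,
    Rcpp,
    stats,
    utils,
    vcfR,
    vegan
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
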