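Package: episelect
Title: Heritable Responses to Selection in Genetically Uniform Plant Accessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for selection experiments on genetically uniform
    Arabidopsis accessions: multi-stratum sequential (Type I) ANOVA with
    orthogonal treatment contrasts and custom error strata, Monte-Carlo power
    simulation over hierarchical designs, genotype-based sample-identity
    quality control that detects accession mix-ups from allele-sharing
    distances, and whole-genome bisulfite methylome differentiation
    statistics (cytosine filtering, differential methylation with FDR
    control, epigenetic distances, and a permutation test of multivariate
    dispersion). Includes synthetic-data generators that emulate the
    block/tray/accession/population/mother structure of such experiments so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
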