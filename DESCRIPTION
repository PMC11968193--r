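Package: migscan
Title: Replicated Resident-Migrant Selection Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies signatures of selection associated with a
    binary life-history phenotype (resident versus migrant) replicated across
    independently derived population pairs. Implements Hudson-style F_ST outlier
    scans at the site and sliding-window level with control-comparison
    exclusion, a PCA-based chi-squared selection statistic, cross-population
    extended haplotype homozygosity (XP-EHH) with rank-based significance,
    gene-proximity annotation, and SNP-level versus gene-level
    parallelism/convergence classification. Ships a Balding-Nichols structured
    population simulator with founder-mosaic recombination and planted hard
    sweeps so that every stage of the pipeline is verifiable against known
    truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
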