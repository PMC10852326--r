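Package: corerecomb
Title: Detecting and Interpreting Homologous Recombination in Bacterial
    Core Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring recent homologous recombination from
    core-genome haplotypes of closely related bacterial strains. Implements a
    pairwise clonal/recombined hidden Markov model with empirical-divergence
    emissions (CP-HMM), an accumulated-transfers mosaic model relating clonal
    fraction to genome-wide divergence, cohort-level transfer-rate and
    transfer-length statistics with resampling nulls, run-of-shared-ancestry
    and haplotype-sharing-landscape selection scans, within-host dual
    colonization and gene-specific sweep detection, and neutral pair and
    forward-time Moran gene-conversion simulators that supply validation
    oracles and null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
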