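Package: pathosig
Title: Pan-Pathogen Microarray Signature Detection for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel pan-pathogen microarrays
    (PathoChip-style designs) screened against a common human reference
    channel. Computes per-array scale factors from human reference probes,
    normalizes microbial probe signals to the log2 scale, detects probes
    significantly elevated in case groups versus controls with joint
    false-discovery-rate, fold-change and prevalence filters, aggregates
    probes into organism-level microbial signatures, partitions signatures
    into unique and shared sets across case groups, clusters samples on
    their signature profiles with Calinski-Harabasz selection of the
    cluster count, and associates signatures and clusters with clinical
    outcomes. Includes a synthetic-data generator with planted signatures
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
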