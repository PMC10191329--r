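Package: trfdecay
Title: Classification and Turnover Kinetics of tRNA-Derived Small RNAs
Version: 0.1.0
Authors@R:
    person("Jordan", "Hale", email = "jordan.hale@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the turnover of tRNA-derived small RNAs
    (tRFs) from small-RNA sequencing data. Provides positional
    classification of collapsed small-RNA sequences against pre-tRNA gene
    models (tRF-leader, tRF-1, tRF-5, tRF-3, intron-tRF, misc-tRF, miRNA),
    decay-profile-normalised half-life estimation from transcription
    shut-off (actinomycin D) time courses with exponential curve fitting,
    Argonaute RIP versus input enrichment summaries, strand-aware metagene
    coverage profiles anchored at tRNA gene boundaries, and a fully
    deterministic synthetic-data generator with known ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
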