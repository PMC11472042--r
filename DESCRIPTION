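Package: dffchip
Title: Fragment-Level Analysis of DFF Footprinting Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paired-end fragment libraries produced by DNA
    Fragmentation Factor (DFF) digestion followed by chromatin
    immunoprecipitation. Reads and deduplicates BEDPE/BED/SAM fragments,
    builds coverage tracks and replicate correlations, calls ChIP-Seq peaks
    by 25-bp binning with valley-rule resolution and Gaussian summit
    refinement, calls fragment-center clusters for transcription-factor
    footprint detection, builds fragMap (size-by-position) matrices, sorted
    coverage heatmaps and fragment-center profiles around oriented anchors,
    scans genomes with position weight matrices using exact dynamic-
    programming p-values, and simulates footprint-fragment libraries with
    known truth.
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
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
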