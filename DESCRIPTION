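Package: synendure
Title: Synaptic Endurance and Nerve-Terminal Bioenergetics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of synaptic vesicle recycling and
    presynaptic ATP dynamics under metabolic stress. Implements the
    endocytic-block (EB) statistic on pHluorin fluorescence traces, the
    rounds-to-arrest synaptic endurance assay with censoring, ratiometric
    ATP-biosensor phase decomposition (baseline/drop/recovery), and
    culture-normalized immunofluorescence quantification (glycogen-glycogen
    synthase correlation, TH+/TH- ratios, treatment effects), together with
    a seeded mechanistic generator of synthetic pHluorin traces, two-channel
    ATP-sensor traces and multi-channel immunofluorescence images driven by
    a nerve-terminal glycogen/ATP model, so that every analysis stage is
    testable end-to-end without experimental recordings. Group comparisons
    use the Wilcoxon-Mann-Whitney rank test with exact enumeration for
    small samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
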