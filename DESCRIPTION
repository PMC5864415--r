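Package: katharoseq
Title: Control-Based Sample Exclusion for Low-Biomass Microbiome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality control for low-biomass microbiome experiments built on
    titrated positive controls and negative controls. Fits the allosteric
    sigmoidal (Hill) model to control compositions to estimate the background
    contamination load in cell equivalents (the half-saturation constant),
    determines per-study limits of detection by rank tests with
    Benjamini-Hochberg FDR control, derives read-count sample-exclusion
    thresholds from the fitted curve or from the maximum-input control median,
    applies and reports the exclusion, and summarises well-to-well
    contamination. Includes a synthetic titration-experiment generator so the
    whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
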