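Package: plateomics
Title: Analysis of Automated 96-Well Multi-Omics Screening Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-analysis layer for automated microplate multi-omics
    screens of microbial cultures. Processes plate-reader growth curves with
    dye-based volume-loss and background correction, estimates specific and
    maximum growth rates, derives uptake and secretion rates from
    single-time-point dilution series, performs isotope-dilution metabolite
    quantification with biomass normalization and adenylate energy charge,
    computes plate-level quality-control statistics (replicate CV, proteome
    coverage, outlier and contamination detection), and corrects measured
    mass-distribution vectors of derivatized proteinogenic amino acids for
    natural isotope abundance. A synthetic plate simulator with known ground
    truth makes every pipeline stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
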