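Package: embryokin
Title: Cleavage Kinetics and Metabolic Profiling of Cloned and Fertilized Mouse Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing division-timing (morphokinetic) data from
    time-lapse imaging of pre-implantation mouse embryos, comparing cloned
    (somatic-cell nuclear transfer) embryos with fertilized (intracytoplasmic
    sperm injection) controls. Provides lineage-tree validation and timing
    feature extraction (division times, cell-cycle lengths, inter-stage
    durations), exact rank-sum and Fisher tests, an exhaustive axis-aligned
    window classifier maximizing the F-score for predicting blastocyst
    formation, amino-acid turnover computation from spent culture media with
    rank-correlation/Ward hierarchical clustering, and a calibrated stochastic
    simulator of cleavage-lineage cohorts and spent-media datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
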