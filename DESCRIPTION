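Package: thermhr
Title: Thermal-Dose Analysis of Homologous Recombination Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of hyperthermia experiments that probe DNA
    repair by homologous recombination. Provides a RAD51 focus-counting
    pipeline for EdU-gated nuclei in fluorescence Z-stacks (maximum
    projection, maximum-entropy thresholding, particle analysis, focus
    morphology classification), clonogenic survival analytics
    (plating efficiency, linear-quadratic fits, shared-versus-separate
    curve F-tests), immunoblot densitometry (baseline-subtracted band
    quantification, loading-control and reference normalization,
    ANOVA with Tukey HSD, solubility-fractionation comparisons), and
    seeded synthetic-data generators with known ground truth for all
    three assay types.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    readr,
    stats,
    tiff,
    EBImage,
    yaml,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
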