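Package: glucovar
Title: Interpretation of Nonsynonymous Glucokinase Variants from Kinetics,
    Predictor Scores and Evolutionary Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for interpreting missense variants of human
    glucokinase (GCK), the pancreatic beta-cell glucose sensor. Fits Hill,
    Michaelis-Menten and dose-response models to enzyme assay data and derives
    the relative activity index (RAI) and the threshold for glucose-stimulated
    insulin release (GSIR-T) under a configurable heterozygous beta-cell model;
    calibrates evidence-based decision thresholds for variant-effect predictor
    scores from the score distribution of normoglycemic variants; evaluates
    predictors per phenotype, GSIR-T and Hill-coefficient class; combines
    scores by ternary transformation and a two-dimensional region classifier;
    profiles evolutionary conservation with Grantham variation and deviation;
    and generates synthetic variant tables, assays and alignments with known
    ground truth for validation.
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
    minpack.lm,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
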