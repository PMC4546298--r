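Package: chromabind
Title: Chromatin State and DNA Structure Features for Transcription
    Factor Binding Region Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying transcription factor (TF) bound versus
    unbound genomic regions in yeast from three feature families: sequence
    motif features from position weight matrix (PWM) scanning with exact
    score p-values, chromatin-state features extracted from ChIP-chip style
    signal tracks, and DNA-structure features derived from principal
    component analysis of dinucleotide physical properties. Includes
    balanced dataset construction with motif-centered 60 bp region
    refinement, random-forest model evaluation by repeated cross-validation,
    drop-column feature importance, cross-DNA-binding-domain transfer
    evaluation with bootstrap significance, a three-feature intrinsic
    property model, time-lagged co-expression coherence testing of predicted
    bound gene sets, and a synthetic-data generator that emulates the
    statistical structure of all pipeline inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    randomForest,
    stats,
    utils,
    readr,
    stringr,
    generics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
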