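Package: thermoleaf
Title: Drought Classification from Leaf-Level Thermal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A hybrid image-processing and machine-learning pipeline that turns
    handheld leaf-level radiometric thermal images (per-pixel temperature grids
    in CSV) into a well-watered versus dry-down drought classification. Stages:
    FFT high-pass filtering with removal of the dominant (DC) Fourier
    component, gradient-magnitude computation, leaf-mask segmentation by
    interquartile-range (Tukey) fence binarization with morphological
    refinement and largest-component selection, robust extraction of nine
    statistical thermal indicators, two-sample Kolmogorov-Smirnov feature
    screening, and random-forest and multilayer-perceptron classification
    pipelines with stratified splitting, standardization, mutual-information
    feature selection and random-search hyperparameter tuning under stratified
    k-fold cross-validation. Includes a synthetic thermal leaf-scene generator
    with ground-truth masks so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    EBImage,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
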