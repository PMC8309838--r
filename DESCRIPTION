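Package: thermoga
Title: Evolutionary Model and Feature Selection for Breast Thermography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-stage evolutionary ensemble for classifying breast
    thermography exams. A genetic algorithm first evolves nu-SVM
    hyperparameter configurations over a discrete grid (a "bucket of
    models") and returns the ten best-adapted models; a second genetic
    algorithm with binary chromosomes then evolves feature subsets scored
    by those models, returning the smallest best-performing subset and a
    final classifier. Includes the thermal-image texture stack that feeds
    the ensembles (masked gray-level co-occurrence features, local ternary
    pattern spectra, Daubechies wavelet/fractal composites with Higuchi,
    Petrosian and Hurst estimators), seeded synthetic generators for
    two-class ROI pairs and Gaussian feature tables, and plain-text
    readers/writers for ROI temperature matrices and feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    readr,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
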