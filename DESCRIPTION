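Package: plsbd
Title: Density-Ratio Anomaly Detection with Scaled Bregman Divergences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel density-ratio anomaly detection for one-dimensional and
    multivariate time series and tabular data. Fits a Gaussian-kernel model of
    the relative density ratio between an anomaly-free training block and a
    possibly contaminated test sample, with closed-form parameter learning
    under both least-absolute-deviation (L1) and ridge-regularised
    least-squares (L2) objectives and k-fold cross-validation over the kernel
    width and regularisation strength. Windows of the test series are scored
    with the Pearson-like scaled Bregman divergence (PLsBD) or the
    alpha-relative Pearson divergence (the uLSIF score at alpha = 0),
    max-normalised, and thresholded to flag anomaly candidates. Includes
    seeded synthetic-data generators, ROC/AUC and confusion-matrix
    evaluation with window-tolerant matching, CSV readers for the Yahoo-S5
    time-series dialect and labelled feature matrices, ggplot2 visualisations,
    and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
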