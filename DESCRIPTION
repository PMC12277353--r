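Package: fracspec
Title: Fractional-Derivative Spectral Chemometrics for Leaf Potassium Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for estimating leaf potassium content from
    hyperspectral reflectance. Implements the discrete Grunwald-Letnikov
    fractional derivative for uniformly sampled spectra with an order sweep,
    band-wise correlation analysis against potassium content, a NIPALS partial
    least squares regression (PLS1) latent-variable extractor with a cumulative
    explained-variance stopping rule, and fusion regressors that chain the PLSR
    extractor to tuned random-forest, gradient-boosted-tree and feed-forward
    network back ends. A calibrated synthetic spectra generator emulates the
    statistical structure of field leaf spectra so that every stage of the
    analysis is testable without proprietary data.
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
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
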