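Package: specindexnet
Title: Interpretable Spectral Band Selection and Photosynthetic Capacity
    Estimation from Leaf Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates leaf photosynthetic capacity (maximum carboxylation
    rate Vcmax and maximum electron transport rate Jmax) from 400-1000 nm
    hyperspectral reflectance. Implements a band-selecting neural network
    ("Indexfindnet") whose attention heads pick discrete wavelengths via a
    uniform-Gumbel softmax and combine them through learned vegetation-index
    forms, together with the supporting preprocessing (Savitzky-Golay
    smoothing, power compression, cubic-spline band resampling), classic
    two-band vegetation-index screens, baseline regressors (SVR, PLSR, 1-D
    CNNs), interpretation tools (sensitive-band histograms, index-form
    importances), and a synthetic leaf-spectrum generator with a planted
    spectral-index link for fully self-contained testing. Includes a small
    reverse-mode automatic-differentiation engine so that all models train
    on a plain CPU with no external deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
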