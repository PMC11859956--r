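Package: affectau
Title: Valence and Arousal Estimation from Facial Action Unit Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates dimensional affect (valence and arousal) from facial
    action-unit (AU) intensity time series. Provides readers for OpenFace-style
    AU tables, one-second five-frame windowing, gated recurrent unit (GRU)
    regressors trained separately for valence and arousal, leave-one-out
    cross-validation with Fisher-z inference, drop-column feature importance
    with relative-error normalisation, a category/AU-based dimensional
    baseline, and seeded synthetic-data generators with known AU-to-affect
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
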