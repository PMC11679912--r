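Package: sctqc
Title: Ground-Truth-Free Quality Control for Synthetic CT via Slice-Wise
    MAE Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the per-slice Mean Absolute Error (MAE, in Hounsfield
    units) of synthetic CT volumes without access to a ground-truth CT, using
    a two-step cascade of one MAE-interval classifier and four
    interval-specific regressors routed by the classifier. Produces a
    slice-constant "predicted MAE" overlay volume for clinical review, plus
    prediction-deviation (PD/APD) evaluation reports when ground truth is
    available retrospectively. Ships a head-like digital phantom generator
    with exact per-slice MAE control so the entire pipeline can be trained
    and tested at desk scale with no patient data, a compact neural-network
    trainer (convolutional and dense layers, cross-entropy and MSE losses,
    L1+L2 regularisation, Adam), quartile-based MAE binning with boundary
    relaxation, and NIfTI/MetaImage volume I/O.
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
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
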