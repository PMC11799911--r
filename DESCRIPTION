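Package: dcernn
Title: Recurrent Networks with Monte Carlo Dropout for DCE-MRI Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts extended Tofts pharmacokinetic parameters (kep, ve, vp,
    bolus arrival time, and derived Ktrans) from dynamic contrast-enhanced MRI
    concentration curves using stacked LSTM/GRU sequence regressors with Monte
    Carlo dropout for predictive uncertainty, alongside a constrained nonlinear
    least-squares baseline. Includes the population arterial input function
    with dispersion and bolus-delay transforms, a synthetic-data simulator with
    a geometric PSNR noise schedule, concordance and normalized-error
    evaluation statistics, and a variable flip angle signal-to-concentration
    chain for producing pixel-wise parameter and uncertainty maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    pracma,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
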