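Package: ramlibs
Title: Chemometric Classification Pipeline for Hybrid Raman and LIBS Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end chemometric pipeline for classifying materials
    (e.g. food products) from paired Raman and laser-induced breakdown
    spectroscopy (LIBS) measurements acquired on a shared spectrometer.
    Provides exact wavelength/Raman-shift axis conversions, a synthetic
    spectrum generator emulating the two modalities (Lorentzian atomic
    emission lines, Gaussian Raman bands, fluorescence baseline, plasma
    fluctuation), asymmetric-least-squares baseline removal,
    Savitzky-Golay denoising, Lorentzian fitting and subtraction of
    interfering emission lines, early and late spectral data fusion,
    univariate ANOVA filtering, an elastic-net multinomial logistic
    regression solver (cyclic coordinate descent) used jointly for feature
    selection and classification, and repeated stratified k-fold
    cross-validation with confusion-matrix summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    minpack.lm,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
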