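Package: ssvepcvd
Title: SSVEP-Based EEG Screening for Color Vision Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for diagnosing red-green color vision
    deficiency (CVD) from frequency-tagged EEG. Ishihara plate pairs are
    presented with squares flickering at 15 and 18 Hz; the attended plate is
    decoded from the steady-state visual evoked potential (SSVEP) using Welch
    power spectral density and canonical correlation analysis with harmonic
    reference banks. The package reads OpenBCI-GUI style text recordings,
    simulates frequency-tagged cohorts with a behavioral plate-choice model,
    implements the preprocessing chain (Butterworth band-pass, 60 Hz notch,
    average re-reference, trigger-based epoching, amplitude artifact
    rejection, trial averaging), assembles per-subject PSD+CCA feature
    matrices, issues rule-based per-session and per-subject calls with a
    hidden-digit severity score, and evaluates SMOTE-balanced decision tree,
    k-nearest-neighbor and polynomial-kernel SVM classifiers under stratified
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
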