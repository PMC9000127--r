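Package: nifECG
Title: Hybrid ICA-Adaptive Extraction of the Non-Invasive Fetal
    Electrocardiogram
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of the fetal electrocardiogram (fECG) from
    multichannel transabdominal recordings with a hybrid system: a
    non-adaptive independent component analysis (ICA) block estimates the
    maternal component (mECG*) and a maternal-suppressed abdominal
    component (aECG*), and an adaptive cancellation block (LMS,
    Sign-Error LMS, ADALINE, RLS, or a fast transversal filter) removes
    the residual maternal interference; the filter's error signal is the
    estimated fECG.  Includes band-pass preprocessing, a continuous
    wavelet transform fetal QRS detector, Se/PPV/F1 beat scoring against
    reference annotations, fetal heart-rate trace derivation, grid-search
    optimization of the adaptive control parameters on F1 surfaces, a
    channel-subset search, a parametric synthetic abdominal ECG generator
    with ground-truth beats, and WFDB/CSV input and output.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
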