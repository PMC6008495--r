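Package: tfarr
Title: Taylor-Fourier Mode Decomposition and Detection of Ventricular
    Arrhythmia from ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes single-lead electrocardiogram (ECG) frames into
    oscillatory modes with a digital Taylor-Fourier filter bank (least-squares
    projection onto harmonic carriers with polynomial envelopes), computes
    per-mode magnitude and phase-difference features, and classifies
    life-threatening ventricular arrhythmia (shockable rhythm, ventricular
    fibrillation, ventricular tachycardia) with a least-squares support
    vector machine.  Includes a seeded synthetic rhythm generator for
    normal-sinus, VT- and VF-like waveforms, readers for plain-text and
    WFDB-style records, zero-phase band-pass preprocessing, stratified
    hold-out and k-fold evaluation, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
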