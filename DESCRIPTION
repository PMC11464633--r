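Package: marphysio
Title: Electrophysiology of Music-Assisted Relaxation in Intensive Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for multimodal electrophysiological recordings
    (8-channel EEG, single-lead ECG, facial EMG) acquired before, during and
    after music-assisted relaxation sessions with ICU burn patients. Implements
    EEG band power via Welch spectra and Simpson integration with baseline
    z-scoring, heart-rate-variability analysis (time-domain, Poincare SD1/SD2,
    LF/HF spectral balance on the 4-Hz resampled tachogram), surface-EMG RMS
    amplitude and mean-frequency analysis, two-sample permutation testing with
    Benjamini-Hochberg FDR, clinical VAS/HADS summaries, a BIDS-EEG style
    session reader/writer, and a synthetic-session generator with known ground
    truth so every stage is verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
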