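Package: carotidwave
Title: Carotid Ultrasound Waveform Analysis and Wave-Reflection Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of high-frequency carotid artery
    ultrasound recordings in mice. Provides a synthetic-data generator for
    M-mode wall-motion images, pulsed Doppler spectrograms and longitudinal
    cohorts with known ground truth; trace extraction (wall outlining,
    maximum-velocity envelope tracing); cardiac-cycle segmentation with
    arrhythmia rejection and ensemble averaging; hemodynamic metrics
    including QA-loop pulse wave velocity, forward/reflected wave
    separation, the first-harmonic reflection coefficient, pulsatility
    index and Moens-Korteweg Young's modulus; and the longitudinal
    statistical battery (linear mixed-effects models with releveled
    post-hoc contrasts, ROC/AUC with Youden cut-offs) used to screen for
    early sex-specific imaging biomarkers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    lme4,
    pROC,
    jsonlite,
    yaml,
    tiff,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
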