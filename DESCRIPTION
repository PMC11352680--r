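Package: emgtaste
Title: Taste-State Recognition from Facial Surface Electromyography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for recognising electronically evoked taste states from
    multichannel facial surface electromyography (sEMG). Provides a labelled
    synthetic-signal generator emulating the statistical structure of
    taste-stimulation recordings (band-shaped muscle activity, baseline drift,
    powerline interference and harmonics, motion artifacts, amplitude
    excursions), a preprocessing chain (sliding-window segmentation, polynomial
    detrending, zero-phase Butterworth high-pass filtering, adaptive powerline
    notch filtering, abnormal-amplitude rejection), a 126-dimensional
    time/frequency feature set (13 spectral band averages, frequency centroid
    and moments, RMS, zero-crossing rate, mean absolute value, kurtosis and
    skewness per channel), and cross-validated random-forest evaluation
    experiments: stratified k-fold accuracy, incremental feature sweeps,
    exhaustive participant-subset grouping, and paired scenario comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    randomForest,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
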