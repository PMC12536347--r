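Package: cogload
Title: Cognitive-Load Classification from Multimodal Wearable Biosignals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, preprocessing and evaluation pipeline for mental
    workload (cognitive load) classification from consumer wearable
    recordings. Generates synthetic multi-device sessions (four-channel EEG
    at 256 Hz, photoplethysmography, electrodermal activity, skin
    temperature and motion channels) driven by a latent load state; reads
    and writes per-device CSV exports; synchronises devices from a shake
    burst; notch-filters power-line interference and cuts 60 s windows; and
    extracts a 754-entry feature bank (multilevel discrete wavelet
    transform statistics, FFT band powers, engagement/workload indices,
    heart-rate-variability, electrodermal and temperature features).
    Mental-workload labels on a five-point scale are mapped to 2/3/5-class
    problems and evaluated with leave-one-participant-out and personalised
    stratified k-fold cross-validation over standard classifier
    hyperparameter grids, reporting minimum/mean/maximum weighted F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    rpart,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    class,
    withr,
    optparse
Config/testthat/edition: 3
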