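Package: prditherm
Title: Non-Contact Detection of Post-Regurgitation Deep Inhalation from
    Nostril Thermography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts breathing signals from nostril-region infrared
    thermography, detects inspiratory (breath-minimum) events, labels them
    against regurgitation annotations using a 3-second post-regurgitation
    window, and fits a depth-threshold classifier separating
    post-regurgitation deep inhalations (PRDI) from ordinary inhalations
    (NRI). Includes the full signal chain (band-pass filter, z-score
    standardization, centered moving average, local-minima detection),
    evaluation statistics (Mann-Whitney U, ROC/AUC, G-mean, balanced
    accuracy, plateau-midpoint threshold selection), readers and writers for
    the pipeline's file formats, and a seeded simulator of ground-truthed
    synthetic nostril-temperature recordings so every stage is testable
    without original footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
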