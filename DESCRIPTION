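Package: pulseco
Title: Cardiac Output Estimation from Single-Cycle Arterial Pressure Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates a seeded two-subpopulation virtual hemodynamic cohort
    (three-element Windkessel aortic pressure synthesis with tube-load
    propagation to tonometry-ready peripheral sites), preprocesses single-cycle
    pressure waveforms into fixed-length calibrated or amplitude-normalized
    vectors, corrupts them with Gaussian-plus-spike measurement noise, and
    trains compact one-dimensional convolutional neural networks to regress
    cardiac output from waveform shape. Includes two-component Gaussian
    mixture recovery of the cohort structure, Bland-Altman and related
    method-comparison statistics, and an orchestrator for the full
    site x calibration x noise experiment grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
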