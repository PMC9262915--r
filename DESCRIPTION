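Package: hippoquant
Title: Quantitative Analysis of Hippocampal Inhibition, Oscillations and
    Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the quantitative stages of a hippocampal
    inhibition study: spontaneous IPSC event detection from voltage-clamp
    traces, sharp-wave-ripple detection and power in baseline-SD units
    (including a multi-session common-threshold mode), theta/gamma band-power
    estimation with Welch-Hamming spectra and line-noise interpolation,
    isosbestic-corrected fiber-photometry dF/F with locomotion coupling
    analysis, novel-object-location scoring, and staining-intensity,
    perineuronal-ring and mRNA-dot quantification on annotated microscopy
    images. Every analysis stage is paired with a seeded synthetic-data
    generator providing ground truth for detector recovery and calibration
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
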