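Package: tactileAE
Title: Finger-Friction and Acoustic-Emission Analysis of Tactile Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the combined tribological and acoustic-emission (AE)
    characterisation of finger sliding on fabrics and planar substrates, and
    for relating both to sensory-panel ratings. Extracts per-stroke static and
    dynamic coefficients of friction from reciprocating force-plate traces,
    computes windowed AE root-mean-square envelopes and band-limited spectral
    features (90th-percentile magnitude in the 120-160 kHz band), and provides
    the statistical layer: covariance/correlation PCA with concentration
    ellipsoids, Tukey-Kramer all-pairs comparisons, and a combined
    tribology-sensory PCA with supplementary attribute vectors. A synthetic
    data generator with planted ground truth (friction envelopes, stick-slip,
    AE bursts, questionnaire responses) makes every stage testable without
    human-subject recordings.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
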