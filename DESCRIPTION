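Package: afgtools
Title: Auditory Figure-Ground Stimuli, Adaptive Task Simulation and
    Multivariate Analysis of Speech-in-Noise Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for auditory figure-ground (AFG) psychophysics.
    Synthesizes fixed-frequency and speech-pitch-driven (harmonic) dynamic
    figure-ground stimuli built from 50 ms pure-tone chords, processes and
    generates fundamental-frequency (F0) contours, runs transformed up-down
    adaptive staircases (1-up-1-down and 2-down-1-up) with simulated
    psychometric-function observers, and analyses participant score tables
    with Spearman correlations under Holm-Bonferroni correction, stepwise
    regression, and a maximum-likelihood structural equation modelling
    engine with latent variables, fit indices (CFI, TLI, RMSEA, SRMR) and
    subsample-bootstrap RMSEA. Includes a calibrated synthetic-cohort
    generator linking age, pure-tone audiometric average, AFG thresholds
    and speech-in-noise scores so the full analysis pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
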