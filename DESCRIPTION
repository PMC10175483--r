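Package: flickerlearn
Title: Simulation and Analysis of Temporal Perceptual-Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measurement machinery for temporal visual psychophysics and
    steady-state visual evoked potential (ssVEP) experiments of the kind used
    to study flicker-based perceptual learning in amblyopia.  Provides
    parametric two-alternative forced-choice observer models with
    session-to-session learning, transformed up-down (3-down-1-up) adaptive
    staircases for critical flicker fusion and stereo disparity thresholds,
    method-of-constant-stimuli training sessions with maximum-likelihood
    psychometric (logistic) fitting and criterion-threshold extraction,
    synthesis and analysis of 15 Hz ssVEP epochs (spectral amplitude,
    signal-to-noise ratio, cross-correlation interocular delay with
    sub-sample interpolation), pre/post study statistics, and plain-text
    trial-log and EEG file formats tying the stages into one reproducible
    pipeline driven by a synthetic observer generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
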