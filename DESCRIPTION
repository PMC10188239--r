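Package: ergid
Title: System Identification and Latency Analysis for Electroretinogram
    Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing electroretinogram (ERG) responses of insects
    to band-limited Gaussian white-noise and pulse light stimuli. Implements
    stimulus synthesis (filtered white noise, pulse trains), latency
    estimation from pulse responses (half-maximum crossing) and from noise
    stimulation (cross-correlation minimum with sub-sample refinement),
    Welch cross-spectral estimation of linear coherence and gain,
    coherence-weighted fitting of a resonant second-order low-pass filter
    (amplitude, time constant, damping), paired nonparametric condition
    comparisons with Bonferroni correction, and linear mixed-effects
    modelling of the latency-temperature relationship. A synthetic-session
    generator produces complete multi-channel recordings (stimulus, ERG,
    eye temperature, locomotion) with known ground truth for end-to-end
    parameter-recovery validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    minpack.lm,
    lme4,
    lmerTest,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
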