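Package: ioitrf
Title: Inter-Onset-Interval Modulation of Auditory Responses in Continuous Soundscapes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how the amplitude of auditory evoked responses
    (N1/P2) depends on the inter-onset interval (IOI) between sound events in
    continuous, naturalistic soundscapes.  Detects acoustic onsets from raw
    audio via energy, spectral-flux and complex-domain novelty functions with
    adaptive-threshold peak picking; bins onsets by IOI with uniform event
    counts; estimates lagged linear forward models (temporal response
    functions) by ridge regression with segment-based cross-validation;
    extracts N1/P2 peaks per bin, fits amplitude-versus-IOI curves, and tests
    IOI modulation with a bin-allocation permutation test; compares model
    classes under matched training data.  Includes a synthetic-data generator
    (onset trains, tone-burst audio, multichannel EEG with an IOI-dependent
    biphasic kernel) so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
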