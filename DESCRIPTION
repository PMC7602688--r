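Package: tvawr
Title: Whole-Report Modelling of Visual Attention Capacity, Speed and
    Threshold
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of Theory of Visual Attention
    (TVA) parameters from whole-report letter data: a probability
    distribution over visual short-term memory capacity K, total
    processing speed C (Hz), perceptual threshold t0 (ms) and the
    additional effective exposure mu (ms) credited to unmasked displays.
    Includes a race-process trial simulator and synthetic cohort
    generators (case-control, repeated-session, training-curve designs),
    plus the downstream statistical pipeline used in clinical attention
    studies: case-control linear models with Cohen's d effect sizes,
    clinical-association models, one-way intraclass correlation
    reliability, per-subject slope extraction, principal-component
    training-gain scores and linear mixed-effects session-by-group
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
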