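Package: voicevitals
Title: Voice-Based Vitality and Mental-Activity Monitoring from Call Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for voice-based longitudinal mental-health monitoring:
    utterance segmentation of call audio by amplitude thresholding with hold
    times, autocorrelation fundamental-frequency tracking, a documented
    prosody-to-emotion affect layer, per-call vitality scores, a 14-day
    moving-average "mental activity" index with validity filters, cohort
    analysis-dataset construction, retention curves, normality goodness-of-fit
    with effect sizes, sex-stratified comparisons with Cohen's d, score
    correlations, regional pre/post event-window analysis, and seeded
    generators for speech-like audio and longitudinal cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
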