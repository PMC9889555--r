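Package: sceda
Title: Single-Case Experimental Design Data Collection and Effect-Size Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for structured behavioral data collection and automatic
    effect-size analysis of single-case experimental designs (SCEDs). Provides
    domain types and validation for AB designs with an optional generalization
    phase, a six-item measure system with frequency, duration and interval
    recording procedures, non-overlap effect-size indices (NAP, PND, PEM,
    Tau-AB, Tau-U) with an exhaustive pairwise oracle, a detrended parametric
    regression testing level and slope treatment effects, automatic method
    selection with interpretation bands, milestone and mastery detection, a
    synthetic SCED generator with binomial session noise and a logistic
    acquisition curve, and Monte-Carlo harnesses for type-I error and power.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
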