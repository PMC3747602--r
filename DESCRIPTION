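Package: sdppg
Title: Second-Derivative Photoplethysmogram Analysis and Ageing Index
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates arterial stiffness from single-channel finger
    photoplethysmogram (PPG) recordings via second-derivative (SDPPG)
    waveform analysis. Implements an analysis pipeline that band-limits
    the PPG, differentiates it with smooth noise-robust differentiators,
    normalizes every cardiac recurrence to a common 1 s base, applies an
    equiripple (Parks-McClellan) low-pass filter, aligns recurrences at
    the 50% level of the systolic rising front, ensemble-averages them,
    and detects the five systolic SDPPG waves a-e by fourth-derivative
    zero crossings. Reports the ageing index AGI = (b - c - d - e)/a and
    its beat-to-beat dispersion, provides the low-pass edge-frequency
    optimization sweep that minimizes that dispersion, cohort-level
    AGI-versus-age regression with Bland-Altman and Welch group
    comparison, and a fully annotated synthetic PPG generator used by the
    test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
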