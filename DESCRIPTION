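Package: pulsatile
Title: Pulsatile Vibrotactile Change-Detection Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing yes/no change-detection
    experiments with pulsatile vibrotactile skin-indentation stimuli.
    Synthesises pulse-train waveforms (single-period raised-cosine pulses at
    configurable pulse rate and waveform frequency), builds method-of-
    constant-stimuli session schedules, computes six temporally global
    kinematic intensity formulations (powers of absolute velocity and
    acceleration), fits a four-parameter psychometric mixture model
    (threshold, width, false-alarm rate, lapse rate) by bounded multistart
    maximum likelihood with validity classification and false-alarm-corrected
    threshold extraction, simulates parametric observers coding pulse width,
    pulse rate or an intensity axis (with optional working-memory width
    inflation in gap sessions), and reproduces the downstream analysis chain:
    per-participant fits, validity census, percent-change thresholds, paired
    gap/no-gap comparisons and intensity-axis rescaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
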