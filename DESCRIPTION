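Package: vocsim
Title: Noise-Vocoder Simulation and Automated Intelligibility Scoring for
    Auditory Implant Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A parameterized noise vocoder for acoustic simulation of
    cochlear-implant sound coding, with envelope degradations (channel count,
    channel frequency boundaries, envelope low-pass cutoff, dynamic-range
    limiting, dB-step quantization), speech-shaped-noise generation and SNR
    mixing, automated sentence- and word-list intelligibility scoring with
    optimal word alignment and homophone-aware matching, and an experiment
    harness that evaluates any audio-to-text recognizer over condition grids
    with repetitions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
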