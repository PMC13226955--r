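Package: remloop
Title: Closed-Loop REM Sleep Deprivation: Simulation, Real-Time
    Classification and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free, fully testable re-creation of a closed-loop
    automated REM sleep deprivation system for mice. Generates ground-truth
    hypnograms and state-dependent synthetic EEG/EMG at 1 kHz, extracts
    sliding-window FFT band-power features (theta/delta ratio and normalized
    high-frequency power), calibrates per-animal classification thresholds
    from labeled baseline recordings, simulates the 100 ms fixed-interval
    control loop with TTL-triggered shaker actuation against a probabilistic
    "virtual mouse" plant, and computes the offline validation statistics
    (confusion matrices, per-state recall/F1, state occupancy, geometric-mean
    fold changes with bootstrap confidence intervals, exact paired Wilcoxon
    signed-rank tests) used to quantify REM suppression efficacy.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
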