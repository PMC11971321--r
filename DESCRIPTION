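Package: replaytrace
Title: Interval Learning, Replay and Connectivity Analysis for Intracellular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell current-clamp recordings from
    dual-optogenetic interval-learning experiments in ex vivo cortical
    circuits. Detects spontaneous network (Up-state-like) events with a
    hysteresis voltage-threshold rule, extracts temporal features of evoked
    and spontaneous activity (peak time, slope-threshold event times, center
    of gravity), quantifies spontaneous replay of trained dynamics by
    correlating mean evoked and spontaneous traces within and across
    training conditions, estimates inter-ensemble lags from paired
    recordings by normalized cross-correlation, classifies timed
    prediction-error neurons from red-alone versus red-plus-blue responses,
    and calls monosynaptic connections from EPSP amplitudes in paired probe
    recordings. Includes a seeded synthetic voltage-trace generator with
    colored noise, stylized spikes and condition-specific network envelopes
    so every stage is testable without recorded data.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
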