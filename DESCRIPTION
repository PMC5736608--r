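Package: thetagamma
Title: Theta-Gamma Cross-Frequency Coupling Analysis for Hippocampal-Prefrontal LFP and Spike Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cross-frequency coupling between hippocampal
    theta oscillations and prefrontal gamma oscillations in local field
    potential (LFP) recordings, together with the spike-train analyses that
    accompany them. Implements zero-phase bandpass filtering and Hilbert
    instantaneous phase, two-cycle Morlet wavelet power, phase-binned
    power profiles with the weighted mean resultant length (MRL),
    phase-power comodulograms, n:m phase-phase coupling, gamma-burst peak
    detection with peak-triggered averages and peak-phase histograms,
    spike-gamma phase locking with Rayleigh tests, geometric-mean-normalized
    spike cross-correlograms, coupling-quartile firing-rate analyses, and
    trial-structured session statistics (paired and group contrasts,
    accuracy correlations, Watson-Williams tests). A synthetic LFP/spike
    generator with known ground truth makes every stage testable without
    animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
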