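Package: lfpltp
Title: Local Field Potential Oscillations, Phase-Amplitude Coupling, and
    In Vivo LTP Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vivo rodent electrophysiology:
    Welch-based relative power spectra of continuous local field potential
    (LFP) recordings with band summaries and group averaging; phase-amplitude
    cross-frequency coupling via the composite-signal modulation index,
    comodulograms over phase-frequency by amplitude-frequency grids, and
    theta-gamma summaries with surrogate significance calibration; evoked
    fEPSP sweep quantification (slope, latency, amplitude), inclusion
    criteria, input/output curves, test-stimulus selection, and
    baseline-normalized long-term potentiation (LTP) time courses with
    window statistics and group comparisons. Includes synthetic-data
    generators for cross-frequency-coupled LFPs and evoked-sweep
    experiments so every stage is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
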