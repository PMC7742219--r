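Package: imcoh
Title: Intermuscular Coherence Analysis of Multichannel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify common oscillatory drive to muscle pairs from
    multichannel surface electromyography (EMG). Implements the full
    intermuscular-coherence (IMC) workflow: Chebyshev anti-alias decimation,
    Butterworth high-pass filtering, Hilbert-envelope extraction, epoching by
    movement period, Welch auto-/cross-spectral estimation on concatenated
    trials, magnitude-squared coherence with analytic significance limits
    (including an overlap adjustment via effective segment counts), band-summed
    significant coherence (IMC area), phase-slope time-delay estimation,
    windowed-RMS activation ratios, and repeated-measures inference with
    Holm-adjusted post hoc tests. A synthetic common-drive EMG generator with
    known coupling gains, inter-side delays and period-specific activation
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
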