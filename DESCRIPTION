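Package: rumbleloc
Title: Seismo-Acoustic Localization of Elephant Rumbles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to localize low-frequency elephant vocalizations (rumbles)
    from time-synchronized multi-station seismic and acoustic recordings.
    Implements short-time Fourier spectrograms with structure-tensor
    (coherence) enhancement, spectrogram cross-correlation for
    time-difference-of-arrival (TDOA) estimation with peak-prominence quality
    control, deterministic wavespeed-grid multilateration, Bayesian posterior
    sampling over source position and wavespeed (including a joint bimodal
    variant), residual-based accuracy scoring, comparative summary statistics,
    and a synthetic seismo-acoustic scene simulator with ground truth for
    validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
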