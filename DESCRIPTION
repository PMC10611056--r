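Package: iceemdan
Title: Improved CEEMDAN Decomposition of EEG and Other Nonstationary Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Empirical mode decomposition (EMD), ensemble EMD (EEMD), and the
    improved complete ensemble EMD with adaptive noise (ICEEMDAN) for single-
    and multi-channel real-valued time series such as EEG recordings. The
    sifting core (extrema detection, natural cubic-spline envelopes via a
    no-pivot tridiagonal solve, envelope-mean subtraction) is implemented in
    compiled code and operates on batches of signal-plus-noise realizations.
    Includes a seeded synthetic-fixture generator (an intermittent dual-tone
    test signal and EEG-like surrogates), validation metrics (similarity
    index, reconstruction error, IMF-property checks), readers and writers
    for delimited text, raw binary matrices and EDF recordings, and a
    command-line interface with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
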