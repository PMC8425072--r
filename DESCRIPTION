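Package: psctools
Title: Detection, Simulation and Batch Analysis of Spontaneous Postsynaptic Currents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spontaneous postsynaptic currents (PSCs) in
    voltage-clamp recordings. Implements a stepwise event-detection algorithm
    (Savitzky-Golay smoothing, threshold-based initial search against a running
    trend, backward baseline search, and amplitude-based final acceptance), a
    biexponential quantal-conductance simulator with a precision/recall/F1
    validation harness and smoothing-parameter sweeps, and a batch retrieval
    layer for unit files: wildcard search, group summaries, cumulative relative
    histograms, and two-sample Kolmogorov-Smirnov, t and one-way ANOVA tests.
    Reads and writes the tab-delimited recording, unit-file and whole-data text
    formats, and ships a command-line interface for scripted workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    jsonlite
Config/testthat/edition: 3
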