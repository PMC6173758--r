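Package: isitools
Title: Interspike-Interval Analysis of Spontaneous Afferent Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing spontaneous spike trains from hair-cell
    afferent neurons via their interspike-interval (ISI) statistics.
    Implements renewal-process ISI models built from a refractory period
    (absolute plus exponentially distributed relative part) convolved with
    one of three synaptic excitation-time distributions (exponential,
    gamma-exponential mixture, two-exponential mixture), least-squares CDF
    fitting with AIC/BIC model comparison, quartile-based CDF-error
    decomposition and the L-shape index, serial-correlation statistics
    (SRC(n), recurrence quartile matrix, short/long ISI sequence detection,
    Fano factor), a two-state (slow/fast) Markov switching spike simulator,
    a Monte Carlo synaptic-pool depletion-replenishment simulator with
    multiple heterogeneous release sources, and a synthetic cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    lhs,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
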