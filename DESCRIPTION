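Package: phasenets
Title: Time-Resolved Degree-Degree Correlations in Phase-Synchronization
    Networks from Multichannel Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds functional networks from long-term multichannel
    electrophysiological recordings and follows their topology through time.
    Signals are bandpass filtered, cut into non-overlapping windows, and
    pairwise phase synchrony is estimated per window as the mean phase
    coherence of Hilbert-transform instantaneous phases. Each synchrony
    matrix is thresholded to a binary network of fixed link density, from
    which the degree assortativity and clustering coefficients are computed
    together with Erdos-Renyi finite-size baselines. Metric time courses are
    screened for periodicity with Lomb-Scargle periodograms (robust to
    recording gaps) and split into day/night and pre-ictal/inter-ictal
    epochs for comparison. A Kuramoto-type coupled-oscillator simulator with
    day/night-modulated coupling topology, recording gaps and seizure
    annotations provides ground-truth data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
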