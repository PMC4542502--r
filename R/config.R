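#' Configuration for the coupled-oscillator recording simulator
#'
#' Collects and validates every knob of the synthetic recording generator.
#' The simulated system is a set of Kuramoto-type phase oscillators whose
#' coupling graph cross-fades between a daytime and a nighttime topology on a
#' 24-h wall-clock cycle; observed signals are `sin(phase)` plus Gaussian
#' observation noise. Recording gaps delete samples (as drop-outs do in
#' long-term clinical recordings) and seizure events transiently raise the
#' global coupling strength.
#'
#' @param n_channels number of channels/oscillators (at least 3).
#' @param duration recording duration in seconds (before gap removal).
#' @param sampling_rate sampling rate in Hz.
#' @param base_frequency per-channel centre frequency in Hz: a scalar, a
#'   length-2 range spread evenly across channels, or a length-`n_channels`
#'   vector. The default 9-11 Hz band mimics alpha-range rhythms.
#' @param coupling_strength_high,coupling_strength_low coupling gain K
#'   (rad/s per unit edge weight) at the daytime peak and nighttime trough of
#'   the modulation cycle.
#' @param day_graph,night_graph coupling topology active at the daytime peak
#'   and the nighttime trough: `"hub"`, `"modular"`, or an adjacency matrix
#'   (see [coupling_topology()]).
#' @param modulation_period period of the topology cross-fade in hours.
#' @param peak_hour wall-clock hour at which the day topology has full weight.
#' @param noise_sd standard deviation of additive Gaussian observation noise,
#'   in signal units (signals are unit-amplitude sinusoids).
#' @param gap_intervals recording gaps: 2-column matrix or data frame of
#'   `(onset, end)` times in seconds; samples inside gaps are deleted.
#' @param seizure_events seizure annotations: 2-column matrix or data frame of
#'   `(onset, end)` times in seconds, non-overlapping, within the recording.
#' @param seizure_factor multiplicative boost of the coupling gain during a
#'   seizure event.
#' @param start_time absolute wall-clock start of the recording (`POSIXct` or
#'   a string understood by `as.POSIXct()`); anchors day/night logic.
#' @param seed integer seed; identical configurations with identical seeds
#'   reproduce the recording exactly.
#' @return A validated list of class `"oscillator_config"`.
#' @seealso [generate_record()]
#' @export
oscillator_config <- function(n_channels,
                              duration,
                              sampling_rate = 200,
                              base_frequency = c(9, 11),
                              coupling_strength_high = 20,
                              coupling_strength_low = 2,
                              day_graph = "hub",
                              night_graph = "modular",
                              modulation_period = 24,
                              peak_hour = 14,
                              noise_sd = 0.1,
                              gap_intervals = NULL,
                              seizure_events = NULL,
                              seizure_factor = 3,
                              start_time = "2024-01-06 00:00:00",
                              seed = 1L) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 3) abort("n_channels must be at least 3")
  if (sampling_rate <= 0) abort("sampling_rate must be positive")
  if (modulation_period <= 0) abort("modulation_period must be positive")
  if (coupling_strength_high < 0 || coupling_strength_low < 0) {
    abort("coupling strengths must be non-negative")
  }
  if (duration < 4096 / sampling_rate) {
    abort("duration is shorter than one 4096-sample analysis window; signals would be unusable downstream")
  }

  freq <- as.numeric(base_frequency)
  freq <- switch(as.character(length(freq)),
    "1" = rep(freq, n_channels),
    "2" = seq(freq[1], freq[2], length.out = n_channels),
    {
      if (length(freq) != n_channels) {
        abort("base_frequency must have length 1, 2, or n_channels")
      }
      freq
    }
  )

  day_graph <- resolve_topology(day_graph, n_channels)
  night_graph <- resolve_topology(night_graph, n_channels)
  if (sum(day_graph) == 0 || sum(night_graph) == 0) {
    warn("a coupling graph has no links; channels will evolve independently")
  }

  gap_intervals <- validate_intervals(gap_intervals, duration, "gap_intervals")
  seizure_events <- validate_intervals(seizure_events, duration, "seizure_events")

  structure(
    list(
      n_channels = n_channels,
      sampling_rate = sampling_rate,
      duration = duration,
      base_frequency = freq,
      coupling_strength_high = coupling_strength_high,
      coupling_strength_low = coupling_strength_low,
      day_graph = day_graph,
      night_graph = night_graph,
      modulation_period = modulation_period,
      peak_hour = peak_hour,
      noise_sd = noise_sd,
      gap_intervals = gap_intervals,
      seizure_events = seizure_events,
      seizure_factor = seizure_factor,
      start_time = parse_time(start_time),
      seed = as.integer(seed)
    ),
    class = "oscillator_config"
  )
}

resolve_topology <- function(g, n_channels) {
  if (is.character(g)) {
    coupling_topology(g, n_channels)
  } else {
    A <- as_coupling_matrix(g)
    if (nrow(A) != n_channels) {
      abort("coupling topology size does not match n_channels")
    }
    A
  }
}

# returns a tibble(onset, end) sorted, pairwise disjoint, inside [0, duration]
validate_intervals <- function(x, duration, what) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(tibble(onset = numeric(0), end = numeric(0)))
  }
  x <- as.data.frame(x)
  if (ncol(x) < 2) abort(sprintf("%s must have (onset, end) columns", what))
  iv <- tibble(onset = as.numeric(x[[1]]), end = as.numeric(x[[2]]))
  iv <- dplyr::arrange(iv, .data$onset)
  if (any(iv$end <= iv$onset)) abort(sprintf("%s must have end > onset", what))
  if (any(iv$onset < 0) || any(iv$end > duration)) {
    abort(sprintf("%s must lie within [0, duration]", what))
  }
  if (nrow(iv) > 1 && any(iv$onset[-1] < iv$end[-nrow(iv)])) {
    abort(sprintf("%s must be non-overlapping", what))
  }
  iv
}

#' @export
print.oscillator_config <- function(x, ...) {
  cat(sprintf(
    "<oscillator_config> %d channels @ %g Hz, %.3g h, seed %d\n",
    x$n_channels, x$sampling_rate, x$duration / 3600, x$seed
  ))
  cat(sprintf(
    "  coupling K: %g (day peak) to %g (night), %g h modulation, %d seizure(s), %d gap(s)\n",
    x$coupling_strength_high, x$coupling_strength_low,
    x$modulation_period, nrow(x$seizure_events), nrow(x$gap_intervals)
  ))
  invisible(x)
}
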