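#' Segment a record into non-overlapping analysis windows
#'
#' Cuts each contiguous segment of the record into consecutive,
#' non-overlapping windows of `n_samples` points. Windows never span a
#' recording gap: after every gap the window grid restarts at the segment
#' start, and a trailing remainder shorter than one window is discarded. At
#' the default 4096 samples and 200 Hz each window covers 20.48 s.
#'
#' @param record a [multichannel_record()].
#' @param n_samples window length in samples.
#' @param keep_data if `TRUE` (default) attach the raw samples of every
#'   window as a list-column of `n_samples` x channels matrices.
#' @return A tibble with one row per window: `window_index`, `onset`
#'   (seconds since record start), `start_time` (absolute), `first_row`
#'   (row into `record$samples`) and, optionally, `data`.
#' @export
segment_windows <- function(record, n_samples = 4096, keep_data = TRUE) {
  stopifnot(inherits(record, "multichannel_record"), n_samples >= 1)
  seg <- record$segments
  fs <- record$sampling_rate
  rows <- purrr::pmap(seg, function(onset, n, first_row) {
    nw <- n %/% n_samples
    if (nw == 0) {
      return(NULL)
    }
    w <- seq_len(nw) - 1
    tibble(
      onset = onset + w * n_samples / fs,
      first_row = first_row + w * n_samples
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warn("record is shorter than one window; no windows produced")
    return(tibble(
      window_index = integer(0), onset = numeric(0),
      start_time = record$start_time[0], first_row = integer(0)
    ))
  }
  out <- dplyr::mutate(out,
    window_index = dplyr::row_number(),
    start_time = record$start_time + .data$onset,
    .before = 1
  )
  if (keep_data) {
    out$data <- purrr::map(out$first_row, function(r) {
      record$samples[r:(r + n_samples - 1), , drop = FALSE]
    })
  }
  out
}

#' Instantaneous phases via the analytic signal
#'
#' Computes the instantaneous phase of each channel of one analysis window as
#' the argument of the analytic signal \eqn{x + i H[x]}, with the Hilbert
#' transform \eqn{H} evaluated by FFT over the window (no tapering). The
#' channel mean is removed first: a DC offset shifts the analytic signal off
#' the origin and corrupts the phase. Edge effects of the per-window
#' transform are accepted; the temporal averaging in the mean phase coherence
#' damps their influence.
#'
#' @param window numeric matrix (samples x channels) or vector.
#' @return Matrix (or vector) of phases in radians, same shape as the input.
#'   Channels that are all zero (or constant) have no defined phase: they are
#'   returned as `NA` with a warning, and downstream stages treat them as
#'   excluded.
#' @export
instantaneous_phase <- function(window) {
  vec <- is.null(dim(window))
  x <- if (vec) matrix(window, ncol = 1) else as.matrix(window)
  if (!all(is.finite(x))) abort("window contains non-finite samples")
  n <- nrow(x)
  h <- hilbert_multiplier(n)
  phases <- matrix(NA_real_, n, ncol(x))
  dead <- logical(ncol(x))
  for (ch in seq_len(ncol(x))) {
    xc <- x[, ch] - mean(x[, ch])
    if (all(xc == 0)) {
      dead[ch] <- TRUE
      next
    }
    analytic <- fft(fft(xc) * h, inverse = TRUE) / n
    phases[, ch] <- Arg(analytic)
  }
  if (any(dead)) {
    warn(sprintf(
      "phase undefined for constant channel(s) %s; marked NA and excluded downstream",
      paste(which(dead), collapse = ", ")
    ))
  }
  if (vec) phases[, 1] else phases
}

hilbert_multiplier <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

#' Mean phase coherence of two phase sequences
#'
#' The phase-locking statistic
#' \deqn{R = \left| N^{-1} \sum_{j=0}^{N-1} e^{i(\Phi_a(j) - \Phi_b(j))} \right|}
#' i.e. the modulus of the time-averaged unit phasor of the instantaneous
#' phase difference. `R = 1` for fully phase-locked sequences (any constant
#' offset), `R` near 0 when the phase difference is scattered uniformly.
#'
#' @param phases_a,phases_b numeric phase vectors of equal length (radians).
#' @return A value in `[0, 1]`.
#' @examples
#' mean_phase_coherence(c(0, 1, 2), c(0.5, 1.5, 2.5)) # constant offset -> 1
#' @export
mean_phase_coherence <- function(phases_a, phases_b) {
  if (length(phases_a) != length(phases_b)) {
    abort("phase sequences must have equal length")
  }
  if (length(phases_a) < 1) abort("phase sequences must be non-empty")
  Mod(mean(exp(1i * (phases_a - phases_b))))
}

#' Pairwise phase-synchronization matrix of one window
#'
#' Evaluates the mean phase coherence for every unordered channel pair of a
#' phase window. The diagonal is set to 0 by convention; entries involving a
#' channel whose phase is undefined (`NA` column) are `NA`.
#'
#' @param phases matrix of instantaneous phases, samples x channels.
#' @return Symmetric channels x channels matrix with entries in `[0, 1]`.
#' @export
sync_matrix <- function(phases) {
  phases <- as.matrix(phases)
  nc <- ncol(phases)
  valid <- !colSums(is.na(phases))
  if (sum(valid) < 2) abort("need at least 2 valid channels")
  R <- matrix(NA_real_, nc, nc)
  Z <- exp(1i * phases[, valid, drop = FALSE])
  G <- Mod(t(Conj(Z)) %*% Z) / nrow(phases)
  R[valid, valid] <- G
  R <- (R + t(R)) / 2 # enforce exact symmetry against rounding
  diag(R) <- 0
  R
}

#' Windowed phase-synchronization matrices for a whole record
#'
#' Runs the per-window phase pipeline over a (typically bandpass-filtered)
#' record: segment into `n_samples` windows respecting gaps, extract
#' instantaneous phases per window, and compute the coherence matrix.
#'
#' @inheritParams segment_windows
#' @return A tibble with one row per window (`window_index`, `onset`,
#'   `start_time`) and a list-column `R` of synchronization matrices.
#' @examples
#' cfg <- oscillator_config(n_channels = 4, duration = 90, seed = 2)
#' rec <- generate_record(cfg)$record
#' tc <- rec |> bandpass_filter() |> sync_timecourse()
#' tc$R[[1]][1:3, 1:3]
#' @export
sync_timecourse <- function(record, n_samples = 4096) {
  win <- segment_windows(record, n_samples, keep_data = FALSE)
  win$R <- purrr::map(win$first_row, function(r) {
    x <- record$samples[r:(r + n_samples - 1), , drop = FALSE]
    sync_matrix(instantaneous_phase(x))
  })
  win$first_row <- NULL
  win
}
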