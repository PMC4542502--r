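#' Multichannel recordings with gaps and annotations
#'
#' A `multichannel_record` holds uniformly sampled multichannel signals from
#' which gap intervals have been deleted, so the retained data form a set of
#' contiguous segments at a common sampling rate. Windowing never bridges a
#' segment boundary and all timestamps are absolute wall-clock times, which is
#' what the day/night epoch logic operates on.
#'
#' @param samples numeric matrix, time points x channels. When `segments` is
#'   `NULL` the rows are taken to be contiguous from time 0 and any rows
#'   falling inside `gaps` are deleted.
#' @param sampling_rate sampling rate in Hz.
#' @param start_time absolute time of sample 0 (`POSIXct` or string).
#' @param gaps,annotations data frames with `(onset, end)` columns in seconds
#'   relative to `start_time` (gaps: intervals with no data; annotations:
#'   seizure events).
#' @param segments internal: precomputed tibble of contiguous runs with
#'   columns `onset` (s), `n` (samples) and `first_row` (row index into
#'   `samples`); used when gap deletion already happened upstream.
#' @return An object of class `"multichannel_record"`.
#' @export
multichannel_record <- function(samples, sampling_rate, start_time,
                                gaps = NULL, annotations = NULL,
                                segments = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) abort("samples must be numeric")
  if (sampling_rate <= 0) abort("sampling_rate must be positive")
  total_dur <- nrow(samples) / sampling_rate
  if (is.null(segments)) {
    gaps <- validate_intervals(gaps, total_dur, "gaps")
    keep <- rep(TRUE, nrow(samples))
    t <- (seq_len(nrow(samples)) - 1) / sampling_rate
    for (g in seq_len(nrow(gaps))) {
      keep[t >= gaps$onset[g] & t < gaps$end[g]] <- FALSE
    }
    segments <- runs_to_segments(keep, sampling_rate)
    samples <- samples[keep, , drop = FALSE]
  } else {
    gaps <- validate_intervals(gaps, Inf, "gaps")
    segments <- as_tibble(segments)
    stopifnot(sum(segments$n) == nrow(samples))
  }
  annotations <- validate_intervals(annotations, Inf, "annotations")

  structure(
    list(
      samples = unname(samples),
      sampling_rate = sampling_rate,
      start_time = parse_time(start_time),
      segments = segments,
      gaps = gaps,
      annotations = annotations
    ),
    class = "multichannel_record"
  )
}

parse_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(x)
  }
  as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"
  ))
}

runs_to_segments <- function(keep, fs) {
  r <- rle(keep)
  stop_at <- cumsum(r$lengths)
  start_at <- stop_at - r$lengths + 1
  kept <- which(r$values)
  first_row <- cumsum(c(1, r$lengths[kept]))[seq_along(kept)]
  tibble(
    onset = (start_at[kept] - 1) / fs,
    n = r$lengths[kept],
    first_row = first_row
  )
}

#' @export
print.multichannel_record <- function(x, ...) {
  cat(sprintf(
    "<multichannel_record> %d channels @ %g Hz, %d samples in %d segment(s)\n",
    ncol(x$samples), x$sampling_rate, nrow(x$samples), nrow(x$segments)
  ))
  cat(sprintf(
    "  start %s, %d gap(s), %d seizure annotation(s)\n",
    format(x$start_time, "%Y-%m-%d %H:%M:%S"),
    nrow(x$gaps), nrow(x$annotations)
  ))
  invisible(x)
}

n_channels <- function(record) ncol(record$samples)

#' Write / read a record as plain text
#'
#' Signals go to a wide CSV with a `time_s` column (seconds since record
#' start) and one column per channel; gap structure is implicit in the time
#' column and is reconstructed on read. Annotations and gaps go to CSVs with
#' both relative seconds and ISO-8601 wall-clock timestamps.
#'
#' @param record a [multichannel_record()].
#' @param dir output directory (created if needed).
#' @return `write_record()` returns the paths invisibly; `read_record()`
#'   returns a [multichannel_record()].
#' @export
write_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seg <- record$segments
  time_s <- unlist(purrr::map2(
    seg$onset, seg$n,
    function(o, n) o + (seq_len(n) - 1) / record$sampling_rate
  ))
  sig <- as_tibble(record$samples, .name_repair = ~ paste0("ch", seq_along(.x)))
  sig <- dplyr::bind_cols(tibble(time_s = time_s), sig)
  paths <- c(
    signals = file.path(dir, "signals.csv"),
    annotations = file.path(dir, "annotations.csv"),
    gaps = file.path(dir, "gaps.csv"),
    meta = file.path(dir, "record.json")
  )
  readr::write_csv(sig, paths[["signals"]])
  readr::write_csv(stamp_intervals(record$annotations, record$start_time),
                   paths[["annotations"]])
  readr::write_csv(stamp_intervals(record$gaps, record$start_time),
                   paths[["gaps"]])
  jsonlite::write_json(
    list(sampling_rate = record$sampling_rate,
         start_time = format(record$start_time, "%Y-%m-%dT%H:%M:%S")),
    paths[["meta"]], auto_unbox = TRUE
  )
  invisible(paths)
}

stamp_intervals <- function(iv, start_time) {
  dplyr::mutate(iv,
    onset_time = format(start_time + .data$onset, "%Y-%m-%dT%H:%M:%S"),
    end_time = format(start_time + .data$end, "%Y-%m-%dT%H:%M:%S")
  )
}

#' @rdname write_record
#' @export
read_record <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "record.json"))
  sig <- readr::read_csv(file.path(dir, "signals.csv"),
                         show_col_types = FALSE)
  fs <- meta$sampling_rate
  time_s <- sig$time_s
  samples <- as.matrix(sig[-1])
  # contiguous runs: cadence break where the step exceeds 1.5 sample periods
  brk <- which(diff(time_s) > 1.5 / fs)
  start_at <- c(1, brk + 1)
  stop_at <- c(brk, length(time_s))
  segments <- tibble(
    onset = time_s[start_at],
    n = stop_at - start_at + 1L,
    first_row = start_at
  )
  gaps <- read_intervals(file.path(dir, "gaps.csv"))
  annotations <- read_intervals(file.path(dir, "annotations.csv"))
  multichannel_record(samples, fs, meta$start_time,
                      gaps = gaps, annotations = annotations,
                      segments = segments)
}

read_intervals <- function(path) {
  if (!file.exists(path)) {
    return(tibble(onset = numeric(0), end = numeric(0)))
  }
  iv <- readr::read_csv(path, show_col_types = FALSE)
  tibble(onset = as.numeric(iv$onset), end = as.numeric(iv$end))
}
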