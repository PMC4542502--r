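#' Pipeline configuration
#'
#' Bundles every stage parameter of [run_pipeline()] with the analysis
#' defaults: 1-45 Hz band, 4096-sample windows, link density 0.1, 20
#' Erdos-Renyi null realizations, day 06:00-22:00 / night 22:00-06:00,
#' 4 h pre-ictal phase, 30 min post-seizure exclusion, 4-fold periodogram
#' oversampling.
#'
#' Exactly one input source must be given: `record_dir` (a directory written
#' by [write_record()]) or `oscillator` (an [oscillator_config()] to
#' simulate).
#'
#' @param record_dir directory containing `signals.csv`, `gaps.csv`,
#'   `annotations.csv`, `record.json` (see [read_record()]).
#' @param oscillator an [oscillator_config()] for simulated input.
#' @param low,high bandpass edges (Hz).
#' @param n_samples analysis window length in samples.
#' @param rho link density of the thresholded networks.
#' @param n_null_realizations Erdos-Renyi ensemble size.
#' @param day_start,night_start day/night boundaries (hours of the day).
#' @param preictal_h,post_min pre-ictal phase (hours) and post-seizure
#'   exclusion (minutes).
#' @param oversampling periodogram oversampling factor.
#' @param span display smoothing span in windows.
#' @param seed integer seed for the null ensemble (and any other pipeline
#'   randomness).
#' @param write_signals also write the (possibly simulated) record to the
#'   output directory.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(record_dir = NULL, oscillator = NULL,
                            low = 1, high = 45, n_samples = 4096,
                            rho = 0.1, n_null_realizations = 20,
                            day_start = 6, night_start = 22,
                            preictal_h = 4, post_min = 30,
                            oversampling = 4, span = 30, seed = 1L,
                            write_signals = FALSE) {
  if (is.null(record_dir) == is.null(oscillator)) {
    abort("give exactly one of record_dir or oscillator")
  }
  if (!is.null(oscillator)) stopifnot(inherits(oscillator, "oscillator_config"))
  structure(
    list(
      record_dir = record_dir, oscillator = oscillator,
      low = low, high = high, n_samples = n_samples, rho = rho,
      n_null_realizations = n_null_realizations,
      day_start = day_start, night_start = night_start,
      preictal_h = preictal_h, post_min = post_min,
      oversampling = oversampling, span = span, seed = as.integer(seed),
      write_signals = write_signals
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Chains every stage: (optionally) simulate a recording, bandpass filter,
#' window and compute phase-synchronization matrices, threshold to binary
#' networks, compute assortativity/clustering time courses, the Erdos-Renyi
#' finite-size baseline, periodograms, day/night and seizure-state epoch
#' comparisons, and the assortativity-clustering correlation. Artifacts are
#' written as plain text into `out_dir`; every file carries the configuration
#' hash and seed, and a manifest records per-stage completion and counts. On
#' a stage failure the partial outputs and the manifest (marking the stage
#' failed) are retained and an error is raised.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of class `"pipeline_result"` with the metric
#'   time course, baseline, periodograms, comparisons, correlation, manifest
#'   and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  stamp <- sprintf("# config %s seed %d", hash, config$seed)
  manifest <- list(
    config_hash = hash, seed = config$seed,
    stages = list(), counts = list(), files = list()
  )
  res <- list(manifest = manifest)

  finish_stage <- function(name) {
    manifest$stages[[name]] <<- "ok"
  }
  fail <- function(name, err) {
    manifest$stages[[name]] <<- paste("failed:", conditionMessage(err))
    manifest$complete <<- FALSE
    write_manifest(manifest, out_dir, config)
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(err)))
  }
  manifest$complete <- TRUE

  record <- tryCatch({
    if (!is.null(config$oscillator)) {
      sim <- generate_record(config$oscillator, truth_rho = config$rho)
      res$truth <- sim$truth
      sim$record
    } else {
      if (!dir.exists(config$record_dir) ||
            !file.exists(file.path(config$record_dir, "signals.csv"))) {
        abort(sprintf("input record not found: %s",
                      file.path(config$record_dir %||% "", "signals.csv")))
      }
      read_record(config$record_dir)
    }
  }, error = function(e) fail("input", e))
  finish_stage("input")
  if (isTRUE(config$write_signals)) write_record(record, out_dir)

  metrics <- tryCatch({
    record |>
      bandpass_filter(config$low, config$high) |>
      sync_timecourse(n_samples = config$n_samples) |>
      threshold_networks(rho = config$rho) |>
      network_metrics()
  }, error = function(e) fail("metrics", e))
  finish_stage("metrics")

  metrics <- tryCatch({
    metrics <- label_daynight(metrics, config$day_start, config$night_start)
    label_states(metrics, record$annotations,
                 preictal_h = config$preictal_h, post_min = config$post_min,
                 window_s = config$n_samples / record$sampling_rate)
  }, error = function(e) fail("labels", e))
  finish_stage("labels")

  manifest$counts <- list(
    windows = nrow(metrics),
    windows_a_undefined = sum(!metrics$a_defined),
    daynight = as.list(table(metrics$daynight)),
    state = as.list(table(metrics$state))
  )
  message(sprintf(
    "processed %d windows (%d with undefined assortativity); day %d / night %d; %s",
    manifest$counts$windows, manifest$counts$windows_a_undefined,
    manifest$counts$daynight$day, manifest$counts$daynight$night,
    paste(names(manifest$counts$state), unlist(manifest$counts$state),
          sep = "=", collapse = " ")
  ))

  baseline <- tryCatch(
    er_baseline(n_channels(record), config$rho,
                config$n_null_realizations, seed = config$seed),
    error = function(e) fail("baseline", e)
  )
  finish_stage("baseline")

  temporal <- tryCatch({
    metrics <- moving_average(metrics, "a", span = config$span)
    metrics <- moving_average(metrics, "C", span = config$span)
    list(
      pgram_a = periodogram(metrics, "a", config$oversampling),
      pgram_C = periodogram(metrics, "C", config$oversampling),
      daynight = compare_groups(metrics, "daynight"),
      states = if (nrow(record$annotations) > 0) {
        compare_groups(metrics, "state")
      },
      corr = correlate_metrics(metrics)
    )
  }, error = function(e) fail("temporal", e))
  finish_stage("temporal")

  files <- list(
    metrics = file.path(out_dir, "metrics.csv"),
    periodogram_a = file.path(out_dir, "periodogram_a.csv"),
    periodogram_C = file.path(out_dir, "periodogram_C.csv"),
    baseline = file.path(out_dir, "baseline.json"),
    comparisons = file.path(out_dir, "comparisons.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  tryCatch({
    write_stamped_csv(metrics, files$metrics, stamp)
    write_stamped_csv(temporal$pgram_a, files$periodogram_a, stamp)
    write_stamped_csv(temporal$pgram_C, files$periodogram_C, stamp)
    jsonlite::write_json(
      c(unclass(baseline), list(config_hash = hash)),
      files$baseline, auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(
      list(
        config_hash = hash, seed = config$seed,
        daynight = unclass_row(temporal$daynight),
        states = unclass_row(temporal$states),
        a_C_pearson = temporal$corr$pearson
      ),
      files$comparisons, auto_unbox = TRUE, digits = NA
    )
  }, error = function(e) fail("export", e))
  finish_stage("export")
  manifest$files <- files
  write_manifest(manifest, out_dir, config)

  res$record <- record
  res$metrics <- metrics
  res$baseline <- baseline
  res$periodograms <- list(a = temporal$pgram_a, C = temporal$pgram_C)
  res$comparisons <- list(daynight = temporal$daynight,
                          states = temporal$states)
  res$correlation <- temporal$corr
  res$manifest <- manifest
  res$files <- files
  class(res) <- "pipeline_result"
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d windows; baseline a = %.3f +/- %.3f\n",
    nrow(x$metrics), x$baseline$mean_a, x$baseline$sd_a
  ))
  invisible(x)
}

unclass_row <- function(x) {
  if (is.null(x)) NULL else as.list(as.data.frame(x))
}

write_stamped_csv <- function(df, path, stamp) {
  df <- df[!vapply(df, is.list, logical(1))]
  writeLines(stamp, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

write_manifest <- function(manifest, out_dir, config) {
  manifest$config <- config_to_list(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

# canonical list form (matrices to row lists, POSIXct to ISO) for hashing
# and JSON round-tripping
config_to_list <- function(config) {
  x <- unclass(config)
  if (!is.null(x$oscillator)) {
    osc <- unclass(x$oscillator)
    osc$day_graph <- apply(osc$day_graph, 1, as.numeric, simplify = FALSE)
    osc$night_graph <- apply(osc$night_graph, 1, as.numeric, simplify = FALSE)
    osc$start_time <- format(osc$start_time, "%Y-%m-%dT%H:%M:%S")
    x$oscillator <- osc
  }
  x
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round-trip of a [pipeline_config()] (including an embedded
#' [oscillator_config()]); `config_hash()` is the md5 of the canonical JSON
#' form and stamps every pipeline output.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `config_hash()` a hex string.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  osc <- NULL
  as_mat <- function(m) {
    if (is.matrix(m)) m else do.call(rbind, lapply(m, as.numeric))
  }
  if (!is.null(x$oscillator)) {
    o <- x$oscillator
    osc <- oscillator_config(
      n_channels = o$n_channels, duration = o$duration,
      sampling_rate = o$sampling_rate, base_frequency = o$base_frequency,
      coupling_strength_high = o$coupling_strength_high,
      coupling_strength_low = o$coupling_strength_low,
      day_graph = as_mat(o$day_graph),
      night_graph = as_mat(o$night_graph),
      modulation_period = o$modulation_period, peak_hour = o$peak_hour,
      noise_sd = o$noise_sd,
      gap_intervals = as.data.frame(o$gap_intervals),
      seizure_events = as.data.frame(o$seizure_events),
      seizure_factor = o$seizure_factor,
      start_time = o$start_time,
      seed = o$seed
    )
  }
  pipeline_config(
    record_dir = x$record_dir, oscillator = osc,
    low = x$low, high = x$high, n_samples = x$n_samples, rho = x$rho,
    n_null_realizations = x$n_null_realizations,
    day_start = x$day_start, night_start = x$night_start,
    preictal_h = x$preictal_h, post_min = x$post_min,
    oversampling = x$oversampling, span = x$span, seed = x$seed,
    write_signals = isTRUE(x$write_signals)
  )
}

#' @rdname write_pipeline_config
#' @export
config_hash <- function(config) {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_pipeline_config(config, path)
  unname(tools::md5sum(path))
}
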