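#' Gap-aware centered moving average (display smoothing)
#'
#' Smooths a metric time course with a centered moving average over up to
#' `span` consecutive windows for plotting. Averaging runs only across
#' contiguous runs of windows — a run breaks wherever the spacing between
#' consecutive windows exceeds the window cadence, so no smoothed value ever
#' mixes pre- and post-gap data. Near run edges (and for runs shorter than
#' `span`) the average uses the available points. At the default 30 windows
#' of 20.48 s the smoothing span is 10.24 min.
#'
#' All statistics in this package (medians, correlations, periodograms) are
#' computed on unsmoothed values; smoothing exists for display only.
#'
#' @param tc a `metric_timecourse` tibble (needs `onset` seconds).
#' @param value name of the metric column to smooth.
#' @param span number of windows in the averaging kernel.
#' @param cadence expected spacing of consecutive windows in seconds;
#'   defaults to the smallest observed spacing.
#' @return `tc` with an added `<value>_smooth` column.
#' @export
moving_average <- function(tc, value = "a", span = 30, cadence = NULL) {
  stopifnot(span >= 1, value %in% names(tc))
  y <- tc[[value]]
  run <- contiguous_runs(tc$onset, cadence)
  half_lo <- (span - 1) %/% 2
  half_hi <- span - 1 - half_lo
  run <- factor(run, levels = unique(run)) # keep temporal order when splitting
  smooth <- unlist(lapply(split(seq_along(y), run), function(ii) {
    yi <- y[ii]
    n <- length(yi)
    vapply(seq_len(n), function(i) {
      w <- max(1, i - half_lo):min(n, i + half_hi)
      mean(yi[w], na.rm = TRUE)
    }, numeric(1))
  }), use.names = FALSE)
  smooth[is.nan(smooth)] <- NA_real_
  tc[[paste0(value, "_smooth")]] <- smooth
  tc
}

# run ids of contiguous windows: a break is a spacing > 1.5x the cadence
contiguous_runs <- function(onset, cadence = NULL) {
  if (length(onset) <= 1) {
    return(rep(1L, length(onset)))
  }
  d <- diff(onset)
  cadence <- cadence %||% min(d)
  cumsum(c(1L, as.integer(d > 1.5 * cadence)))
}

#' Lomb-Scargle power at given frequencies
#'
#' Classical normalized Lomb-Scargle periodogram of an unevenly sampled
#' series (the least-squares spectral estimator, with the phase shift
#' \eqn{\tau} that makes the sine and cosine terms orthogonal at each
#' frequency). Power is normalized by twice the sample variance, so for a
#' pure sinusoid the peak grows linearly with the number of points.
#'
#' @param t sample times.
#' @param y values (demeaned internally).
#' @param frequencies frequencies (cycles per unit of `t`) at which to
#'   evaluate the power.
#' @return Numeric vector of non-negative powers.
#' @export
lomb_scargle <- function(t, y, frequencies) {
  stopifnot(length(t) == length(y))
  y <- y - mean(y)
  ssq <- sum(y^2) / (length(y) - 1)
  if (ssq == 0) {
    return(rep(0, length(frequencies)))
  }
  vapply(frequencies, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * ssq)
  }, numeric(1))
}

#' Lomb-Scargle periodogram of a metric time course
#'
#' Demeans the (unsmoothed) metric values and evaluates the normalized
#' Lomb-Scargle periodogram on a frequency grid in cycles/hour, from one
#' cycle per record length up to the pseudo-Nyquist frequency of the window
#' cadence, oversampled by `oversampling`. Because the estimator works on
#' arbitrary sample times, recording gaps need no special handling. Undefined
#' metric values are excluded.
#'
#' @param tc a `metric_timecourse` tibble.
#' @param value metric column name.
#' @param oversampling frequency grid oversampling factor.
#' @return An `ls_periodogram` tibble with columns `frequency` (1/h),
#'   `period` (h) and `power`; the grid step (1/h) is attached as attribute
#'   `grid_step`.
#' @export
periodogram <- function(tc, value = "a", oversampling = 4) {
  keep <- !is.na(tc[[value]])
  t_h <- tc$onset[keep] / 3600
  y <- tc[[value]][keep]
  if (length(y) < 16) abort("need at least 16 defined values for a periodogram")
  t_span <- diff(range(t_h))
  f_min <- 1 / t_span
  f_max <- 0.5 / (median(diff(t_h)))
  df <- 1 / (oversampling * t_span)
  freq <- seq(f_min, f_max, by = df)
  if (var(y) == 0) {
    warn("constant series: periodogram is identically zero")
    power <- rep(0, length(freq))
  } else {
    power <- lomb_scargle(t_h, y, freq)
  }
  out <- tibble(frequency = freq, period = 1 / freq, power = power)
  attr(out, "grid_step") <- df
  attr(out, "oversampling") <- oversampling
  attr(out, "metric") <- value
  class(out) <- c("ls_periodogram", class(out))
  out
}

#' Label windows as day or night
#'
#' Assigns each window to day or night by the wall-clock time of day of its
#' start: day is `[06:00, 22:00)` and night `[22:00, 06:00)` by default.
#'
#' @param tc a `metric_timecourse` tibble with `start_time` (`POSIXct`).
#' @param day_start,night_start boundaries in hours of the day.
#' @return `tc` with an added factor column `daynight`.
#' @export
label_daynight <- function(tc, day_start = 6, night_start = 22) {
  tod <- tod_seconds(tc$start_time) / 3600
  day <- tod >= day_start & tod < night_start
  tc$daynight <- factor(ifelse(day, "day", "night"),
                        levels = c("day", "night"))
  tc
}

#' Label windows by seizure-relative state
#'
#' Classifies every window into exactly one of: `ictal` (the window overlaps
#' a seizure), `pre-ictal` (window start falls in the `preictal_h`-hour
#' interval before a seizure onset), `post-exclusion` (window start within
#' `post_min` minutes after a seizure end — excluded from the inter-ictal
#' reference, but pre-ictal takes precedence when the next seizure is close),
#' or `inter-ictal` (everything else: at least `preictal_h` hours before any
#' onset and `post_min` minutes after any end). Precedence is
#' ictal > pre-ictal > post-exclusion.
#'
#' @param tc a `metric_timecourse` tibble (needs `onset` seconds).
#' @param seizures data frame of seizure `(onset, end)` times in seconds
#'   since record start, sorted and non-overlapping (e.g.
#'   `record$annotations`).
#' @param preictal_h assumed pre-ictal phase duration in hours.
#' @param post_min post-seizure exclusion in minutes.
#' @param window_s window duration in seconds (used for overlap with the
#'   seizure interval); defaults to the smallest window spacing.
#' @return `tc` with an added factor column `state`.
#' @export
label_states <- function(tc, seizures = NULL, preictal_h = 4, post_min = 30,
                         window_s = NULL) {
  n <- nrow(tc)
  state <- rep("inter-ictal", n)
  if (!is.null(seizures) && nrow(seizures) > 0) {
    sz <- validate_intervals(seizures, Inf, "seizures")
    window_s <- window_s %||%
      (if (n > 1) min(diff(tc$onset)) else 0)
    span_end <- max(tc$onset) + window_s
    if (any(sz$onset > span_end) || any(sz$end < min(tc$onset))) {
      warn("some seizures lie outside the recording span; only overlap is used")
    }
    w0 <- tc$onset
    post <- pre <- ictal <- rep(FALSE, n)
    for (s in seq_len(nrow(sz))) {
      ictal <- ictal | (w0 < sz$end[s] & (w0 + window_s) > sz$onset[s])
      pre <- pre | (w0 > sz$onset[s] - preictal_h * 3600 & w0 < sz$onset[s])
      post <- post | (w0 >= sz$end[s] & w0 < sz$end[s] + post_min * 60)
    }
    state[post] <- "post-exclusion"
    state[pre] <- "pre-ictal"
    state[ictal] <- "ictal"
  }
  tc$state <- factor(state, levels = c(
    "ictal", "pre-ictal",
    "post-exclusion", "inter-ictal"
  ))
  tc
}

#' Compare metric distributions between epochs
#'
#' Computes group medians of the unsmoothed metric and the relative change
#' between them: for the day/night axis
#' \eqn{(\bar{a}_{night} - \bar{a}_{day}) / \bar{a}_{day}}, and for the
#' seizure-state axis
#' \eqn{(\bar{a}_{pre} - \bar{a}_{inter}) / \bar{a}_{inter}} (pre-ictal vs.
#' inter-ictal; ictal and post-exclusion windows are left out of this
#' contrast). Undefined metric values are excluded.
#'
#' @param tc a labeled `metric_timecourse` (see [label_daynight()],
#'   [label_states()]).
#' @param by `"daynight"` or `"state"`.
#' @param value metric column name.
#' @return A `group_comparison` object: one-row tibble with `metric`, `axis`,
#'   `group1`, `group2`, `median1`, `median2`, `relative_change`, `n1`, `n2`;
#'   the per-group value distributions are attached as attribute `groups`.
#'   Returns `NULL` with a warning when a group is empty (e.g. no seizures).
#' @export
compare_groups <- function(tc, by = c("daynight", "state"), value = "a") {
  by <- match.arg(by)
  if (!by %in% names(tc)) {
    abort(sprintf("column '%s' not found; label the time course first", by))
  }
  if (by == "daynight") {
    g1 <- "day"
    g2 <- "night"
  } else {
    g1 <- "inter-ictal"
    g2 <- "pre-ictal"
  }
  v <- tc[[value]]
  x1 <- v[tc[[by]] == g1 & !is.na(v)]
  x2 <- v[tc[[by]] == g2 & !is.na(v)]
  if (length(x1) == 0 || length(x2) == 0) {
    warn(sprintf("empty group ('%s' n=%d, '%s' n=%d): no comparison",
                 g1, length(x1), g2, length(x2)))
    return(NULL)
  }
  m1 <- median(x1)
  m2 <- median(x2)
  out <- tibble(
    metric = value, axis = by, group1 = g1, group2 = g2,
    median1 = m1, median2 = m2,
    relative_change = if (m1 != 0) (m2 - m1) / m1 else NA_real_,
    n1 = length(x1), n2 = length(x2)
  )
  attr(out, "groups") <- list(x1, x2) |> stats::setNames(c(g1, g2))
  class(out) <- c("group_comparison", class(out))
  out
}

#' Correlation and joint histogram of assortativity and clustering
#'
#' Pearson correlation between the paired unsmoothed per-window values of two
#' metrics (by default assortativity `a` and clustering `C`; pairs with an
#' undefined value are excluded), together with their 2-D histogram
#' normalized to the maximum bin count.
#'
#' @param tc a `metric_timecourse` containing both metric columns.
#' @param x,y metric column names.
#' @param bins number of histogram bins per axis.
#' @return A `metric_correlation` object: list with `pearson`, `n`, and
#'   `histogram` (tibble of bin midpoints and normalized counts).
#' @export
correlate_metrics <- function(tc, x = "a", y = "C", bins = 50) {
  keep <- !is.na(tc[[x]]) & !is.na(tc[[y]])
  vx <- tc[[x]][keep]
  vy <- tc[[y]][keep]
  if (length(vx) < 3) abort("need at least 3 defined pairs")
  if (var(vx) == 0 || var(vy) == 0) {
    warn("zero variance in a metric: correlation undefined")
    rho <- NA_real_
  } else {
    rho <- cor(vx, vy)
  }
  bx <- seq(min(vx), max(vx), length.out = bins + 1)
  by <- seq(min(vy), max(vy), length.out = bins + 1)
  ix <- pmin(findInterval(vx, bx, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(vy, by, rightmost.closed = TRUE), bins)
  counts <- table(factor(ix, levels = seq_len(bins)),
                  factor(iy, levels = seq_len(bins)))
  hist <- tidyr::expand_grid(xbin = seq_len(bins), ybin = seq_len(bins))
  hist$x_mid <- (bx[hist$xbin] + bx[hist$xbin + 1]) / 2
  hist$y_mid <- (by[hist$ybin] + by[hist$ybin + 1]) / 2
  hist$count <- as.vector(counts)[(hist$ybin - 1) * bins + hist$xbin]
  hist$density <- hist$count / max(hist$count)
  names(hist)[names(hist) == "x_mid"] <- paste0(x, "_mid")
  names(hist)[names(hist) == "y_mid"] <- paste0(y, "_mid")
  structure(
    list(pearson = rho, n = length(vx), metrics = c(x, y), histogram = hist),
    class = "metric_correlation"
  )
}

#' @export
print.metric_correlation <- function(x, ...) {
  cat(sprintf(
    "<metric_correlation> %s vs %s: Pearson rho = %.3f over %d windows\n",
    x$metrics[1], x$metrics[2], x$pearson, x$n
  ))
  invisible(x)
}
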