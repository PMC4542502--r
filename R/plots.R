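#' Plot a metric time course
#'
#' Line plot of the smoothed metric over wall-clock time (smoothing with
#' [moving_average()] is applied if not already present), with gaps left
#' unconnected, seizure onsets as vertical marks when supplied, and the
#' Erdos-Renyi finite-size baseline as a horizontal band when supplied.
#'
#' @param object a `metric_timecourse` tibble.
#' @param value metric column to plot.
#' @param baseline optional [er_baseline()] drawn as mean +/- 1 sd band.
#' @param seizures optional annotation tibble with `onset` (seconds).
#' @param span smoothing span in windows.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.metric_timecourse <- function(object, value = "a", baseline = NULL,
                                       seizures = NULL, span = 30, ...) {
  smooth_col <- paste0(value, "_smooth")
  if (!smooth_col %in% names(object)) {
    object <- moving_average(object, value, span = span)
  }
  object$run <- factor(contiguous_runs(object$onset))
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$start_time, y = .data[[smooth_col]],
                 group = .data$run)
  )
  if (!is.null(baseline)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = min(object$start_time), xmax = max(object$start_time),
      ymin = baseline$mean_a - baseline$sd_a,
      ymax = baseline$mean_a + baseline$sd_a,
      fill = "darkgreen", alpha = 0.25
    ) +
      ggplot2::geom_hline(yintercept = baseline$mean_a, linewidth = 0.3)
  }
  if (!is.null(seizures) && nrow(seizures) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = min(object$start_time) - min(object$onset) + seizures$onset,
      colour = "red", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}

#' Plot a Lomb-Scargle periodogram
#'
#' Power against period (hours, log scale), with reference marks at 24, 12
#' and 8 h where daily rhythms and their subharmonics would appear.
#'
#' @param object an `ls_periodogram` from [periodogram()].
#' @param mark_periods reference periods in hours (empty to disable).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ls_periodogram <- function(object, mark_periods = c(24, 12, 8), ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$period, y = .data$power))
  if (length(mark_periods)) {
    p <- p + ggplot2::geom_vline(xintercept = mark_periods,
                                 linetype = "dotted", colour = "grey50")
  }
  p +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "period (h)", y = "normalized power",
                  title = attr(object, "metric")) +
    ggplot2::theme_minimal()
}

#' Plot the per-group metric distributions of a comparison
#'
#' Overlaid frequency polygons of the two group distributions (e.g. day vs.
#' night assortativity), from the unsmoothed per-window values stored with
#' the comparison.
#'
#' @param object a `group_comparison` from [compare_groups()].
#' @param bins histogram bin count.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, bins = 40, ...) {
  groups <- attr(object, "groups")
  df <- dplyr::bind_rows(lapply(names(groups), function(g) {
    tibble(group = g, value = groups[[g]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, linetype = .data$group)) +
    ggplot2::geom_freqpoly(bins = bins, na.rm = TRUE) +
    ggplot2::labs(x = object$metric, y = "count",
                  title = sprintf("%s: relative change %.3f",
                                  object$axis, object$relative_change)) +
    ggplot2::theme_minimal()
}

#' Plot the joint assortativity-clustering histogram
#'
#' Tile map of the 2-D histogram of per-window metric pairs, normalized to
#' the maximum bin count, annotated with the Pearson correlation.
#'
#' @param object a `metric_correlation` from [correlate_metrics()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.metric_correlation <- function(object, ...) {
  h <- object$histogram
  xc <- paste0(object$metrics[1], "_mid")
  yc <- paste0(object$metrics[2], "_mid")
  ggplot2::ggplot(
    h[h$count > 0, ],
    ggplot2::aes(x = .data[[xc]], y = .data[[yc]], fill = .data$density)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = object$metrics[1], y = object$metrics[2],
      title = sprintf("Pearson rho = %.3f", object$pearson)
    ) +
    ggplot2::theme_minimal()
}
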