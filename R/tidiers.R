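#' Broom-style tidiers
#'
#' `tidy()` returns per-element summaries as tibbles; `glance()` returns
#' one-row overviews.
#'
#' @param x an `er_baseline`, `group_comparison`, `metric_correlation` or
#'   `pipeline_result` object.
#' @param ... unused.
#' @return A tibble.
#' @name phasenets-tidiers
NULL

#' @rdname phasenets-tidiers
#' @export
tidy.er_baseline <- function(x, ...) {
  tibble(
    mean_a = x$mean_a, sd_a = x$sd_a,
    n_realizations = x$n_realizations, n_nodes = x$n_nodes, rho = x$rho
  )
}

#' @rdname phasenets-tidiers
#' @export
glance.er_baseline <- tidy.er_baseline

#' @rdname phasenets-tidiers
#' @export
tidy.group_comparison <- function(x, ...) {
  as_tibble(unclass_row(x))
}

#' @rdname phasenets-tidiers
#' @export
tidy.metric_correlation <- function(x, ...) {
  tibble(
    metric_x = x$metrics[1], metric_y = x$metrics[2],
    pearson = x$pearson, n = x$n
  )
}

#' @rdname phasenets-tidiers
#' @export
tidy.pipeline_result <- function(x, ...) {
  dplyr::bind_rows(
    if (!is.null(x$comparisons$daynight)) tidy(x$comparisons$daynight),
    if (!is.null(x$comparisons$states)) tidy(x$comparisons$states)
  )
}

#' @rdname phasenets-tidiers
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(
    n_windows = nrow(x$metrics),
    n_a_undefined = sum(!x$metrics$a_defined),
    mean_a = mean(x$metrics$a, na.rm = TRUE),
    mean_C = mean(x$metrics$C),
    baseline_mean_a = x$baseline$mean_a,
    baseline_sd_a = x$baseline$sd_a,
    a_C_pearson = x$correlation$pearson,
    config_hash = x$manifest$config_hash,
    seed = x$manifest$seed
  )
}
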