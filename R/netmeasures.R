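#' Degree assortativity of a binary network
#'
#' The assortativity coefficient is the Pearson-type correlation between the
#' degrees at the two ends of links. In terms of the degree sums
#' \eqn{F_u = \sum_n k_n^u} it reads
#' \deqn{a = (F_1 F_3 - F_2^2)^{-1} \left( 2 F_1 \sum_{n > m} A_{nm} k_n k_m - F_2^2 \right),}
#' confined to \eqn{[-1, 1]}. Positive values indicate assortative mixing
#' (links prefer similar degrees), negative values dissortative mixing.
#' For regular graphs (all degrees equal, including the empty graph) the
#' denominator vanishes and the coefficient is undefined: `NA` is returned
#' and such windows are excluded from time averages and histograms.
#'
#' @param net a `"binary_network"` or 0/1 adjacency matrix.
#' @return A single value in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
#' assortativity(path3) # -1: the hub links only to leaves
#' @export
assortativity <- function(net) {
  A <- as_adjacency(net)
  k <- colSums(A)
  f1 <- sum(k)
  if (f1 == 0) {
    return(NA_real_)
  }
  f2 <- sum(k^2)
  f3 <- sum(k^3)
  den <- f1 * f3 - f2^2
  if (den == 0) {
    return(NA_real_)
  }
  link_sum <- sum(A * outer(k, k)) / 2 # sum over n > m of A_nm k_n k_m
  (2 * f1 * link_sum - f2^2) / den
}

#' Clustering coefficients of a binary network
#'
#' The local clustering coefficient of node `n` is the fraction of its
#' neighbour pairs that are themselves linked,
#' \deqn{C_n = [k_n (k_n - 1)]^{-1} \sum_{m,l} A_{nl} A_{nm} A_{ml},}
#' set to 0 for nodes with fewer than two links. `mean_clustering()` averages
#' \eqn{C_n} over all nodes (zeros included).
#'
#' @param net a `"binary_network"` or 0/1 adjacency matrix.
#' @param nodes node indices (default: all).
#' @return `local_clustering()`: vector of values in `[0, 1]`;
#'   `mean_clustering()`: their mean.
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' local_clustering(tri)
#' mean_clustering(tri)
#' @export
local_clustering <- function(net, nodes = NULL) {
  A <- as_adjacency(net)
  k <- colSums(A)
  closed <- diag(A %*% A %*% A) # 2 * triangles through each node
  cn <- ifelse(k > 1, closed / (k * (k - 1)), 0)
  if (!is.null(nodes)) cn[nodes] else cn
}

#' @rdname local_clustering
#' @export
mean_clustering <- function(net) {
  mean(local_clustering(net))
}

#' Erdos-Renyi finite-size baseline for the assortativity coefficient
#'
#' Even ensembles that are degree-degree uncorrelated by construction show
#' nonzero assortativity in finite networks. To calibrate this finite-size
#' effect, an ensemble of random graphs with the same number of nodes and the
#' same link density as the functional networks is generated — with exactly
#' `L = round(rho * M_rs)` links placed uniformly at random among the
#' `M_rs` node pairs, matching the thresholding construction — and the mean
#' and standard deviation of their assortativity is returned.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param rho link density.
#' @param n_realizations ensemble size (default 20).
#' @param seed optional integer seed for reproducible ensembles.
#' @return An object of class `"er_baseline"`: list with `mean_a`, `sd_a`
#'   (sample standard deviation), `n_realizations`, `n_nodes`, `rho`, `seed`.
#' @export
er_baseline <- function(n_nodes, rho, n_realizations = 20, seed = NULL) {
  stopifnot(n_nodes >= 3, rho > 0, rho < 1, n_realizations >= 1)
  m_rs <- n_nodes * (n_nodes - 1) / 2
  L <- round(rho * m_rs)
  if (L < 1) abort("no achievable links at this density")
  pair <- which(lower.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  draw <- function() {
    pick <- sample.int(m_rs, L)
    A <- matrix(0L, n_nodes, n_nodes)
    A[pair[pick, , drop = FALSE]] <- 1L
    assortativity(A + t(A))
  }
  a <- if (is.null(seed)) {
    purrr::map_dbl(seq_len(n_realizations), function(i) draw())
  } else {
    withr::with_seed(seed, purrr::map_dbl(seq_len(n_realizations),
                                          function(i) draw()))
  }
  if (anyNA(a)) {
    warn(sprintf("%d ensemble realization(s) had undefined assortativity; excluded",
                 sum(is.na(a))))
  }
  sd_a <- if (sum(!is.na(a)) > 1) {
    sd(a, na.rm = TRUE)
  } else {
    warn("single-realization ensemble: sd_a set to 0")
    0
  }
  structure(
    list(
      mean_a = mean(a, na.rm = TRUE), sd_a = sd_a,
      n_realizations = n_realizations, n_nodes = n_nodes, rho = rho,
      seed = seed
    ),
    class = "er_baseline"
  )
}

#' @export
print.er_baseline <- function(x, ...) {
  cat(sprintf(
    "<er_baseline> %d ER graphs, %d nodes, rho %g: a = %.4f +/- %.4f\n",
    x$n_realizations, x$n_nodes, x$rho, x$mean_a, x$sd_a
  ))
  invisible(x)
}

#' Are degree-degree correlations genuine or finite-size compatible?
#'
#' A measured assortativity is flagged genuine when it deviates from the
#' Erdos-Renyi ensemble mean by strictly more than one ensemble standard
#' deviation; otherwise it is compatible with finite-size effects alone.
#'
#' @param a assortativity value(s); `NA` propagates.
#' @param baseline an [er_baseline()].
#' @return Logical vector: `TRUE` = genuine.
#' @export
is_genuine <- function(a, baseline) {
  stopifnot(inherits(baseline, "er_baseline"))
  # tiny relative guard keeps the strict boundary convention stable under
  # floating-point rounding of a - mean_a
  abs(a - baseline$mean_a) > baseline$sd_a * (1 + 1e-9)
}

#' Per-window network metrics
#'
#' Computes the assortativity and mean clustering coefficient for every
#' thresholded window.
#'
#' @param tc tibble from [threshold_networks()] with list-column `net`.
#' @return A `metric_timecourse` tibble: `window_index`, `onset`,
#'   `start_time`, `a`, `a_defined`, `C`. Undefined assortativity is kept as
#'   `NA` with `a_defined = FALSE`, never silently dropped.
#' @export
network_metrics <- function(tc) {
  out <- dplyr::mutate(tc,
    a = purrr::map_dbl(.data$net, assortativity),
    C = purrr::map_dbl(.data$net, mean_clustering),
    a_defined = !is.na(.data$a)
  )
  out <- dplyr::select(out, -dplyr::any_of(c("R", "net")))
  class(out) <- c("metric_timecourse", class(out))
  out
}
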