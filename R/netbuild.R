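#' Binarize a synchronization matrix at fixed link density
#'
#' Converts a symmetric synchronization matrix into an undirected binary
#' network with a predefined link density
#' \eqn{\rho = \bar{k} / (N_{rs} - 1)}: the
#' \eqn{L = \mathrm{round}(\rho M_{rs})} largest entries of the lower
#' triangle (out of \eqn{M_{rs} = (N_{rs}^2 - N_{rs})/2} possible links)
#' become links. The realized threshold \eqn{\Theta} is reported as the
#' smallest retained entry. Selection is by rank, so exactly `L` links result
#' for every input and the construction is invariant under monotone
#' transforms of the synchrony values; ties at \eqn{\Theta} are broken
#' deterministically by ascending (row, column) index.
#'
#' @param R symmetric numeric matrix (e.g. from [sync_matrix()]); diagonal
#'   ignored.
#' @param rho target link density in (0, 1); the analysis default is 0.1.
#' @return An object of class `"binary_network"`: a list with the 0/1
#'   adjacency matrix `A`, `rho`, the realized threshold `theta`, and the
#'   link count `L`.
#' @examples
#' R <- matrix(0, 4, 4)
#' R[lower.tri(R)] <- c(0.9, 0.2, 0.7, 0.8, 0.1, 0.3)
#' R <- R + t(R)
#' threshold_to_density(R, rho = 0.5)
#' @export
threshold_to_density <- function(R, rho = 0.1) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (n != ncol(R) || n < 2) abort("R must be a square matrix with >= 2 nodes")
  if (!(rho > 0 && rho < 1)) abort("rho must be in (0, 1)")
  idx <- which(lower.tri(R), arr.ind = TRUE)
  vals <- R[idx]
  if (any(!is.finite(vals))) abort("R contains non-finite entries")
  m_rs <- n * (n - 1) / 2
  L <- round(rho * m_rs)
  if (L < 1) abort("rho too small: no links after rounding")

  ord <- order(-vals, idx[, 1], idx[, 2])
  take <- ord[seq_len(L)]
  A <- matrix(0L, n, n)
  A[idx[take, , drop = FALSE]] <- 1L
  A <- A + t(A)
  net <- structure(
    list(A = A, rho = rho, theta = min(vals[take]), L = L),
    class = "binary_network"
  )
  net
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x$A)
  cat(sprintf(
    "<binary_network> %d nodes, %d links (density %.4g, target rho %g), theta = %.4g\n",
    n, x$L, x$L / (n * (n - 1) / 2), x$rho, x$theta
  ))
  invisible(x)
}

as_adjacency <- function(net) {
  if (inherits(net, "binary_network")) net$A else as.matrix(net)
}

#' Threshold every window of a synchronization time course
#'
#' @param tc tibble from [sync_timecourse()] with list-column `R`.
#' @param rho target link density, see [threshold_to_density()].
#' @return The input tibble with an added list-column `net` of
#'   [threshold_to_density()] results.
#' @export
threshold_networks <- function(tc, rho = 0.1) {
  tc$net <- purrr::map(tc$R, threshold_to_density, rho = rho)
  tc
}

#' Export a binary network as an edge list
#'
#' @param net a `"binary_network"`.
#' @return Tibble of links with 1-based node indices, `from < to`.
#' @export
edge_list <- function(net) {
  A <- as_adjacency(net)
  idx <- which(lower.tri(A) & A > 0, arr.ind = TRUE)
  tibble(from = idx[, 2], to = idx[, 1])
}
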