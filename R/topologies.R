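#' Coupling topologies for the oscillator simulator
#'
#' Build the simple undirected coupling graphs used by [generate_record()].
#' Two stylised families are provided: a hub-dominated graph, in which a few
#' core nodes are wired to every other node (a star-like core with a sparsely
#' connected periphery), and a modular graph of fully connected blocks of
#' unequal size with no links between blocks. These caricature the two
#' organisations hypothesised for wake vs. sleep functional connectivity:
#' integration through hubs vs. segregation into tight clusters.
#'
#' @param type `"hub"` or `"modular"`; alternatively pass an adjacency matrix
#'   directly wherever a topology is accepted.
#' @param n_channels number of oscillators (graph nodes).
#' @param n_hubs for `"hub"`: number of core nodes connected to all others.
#' @param block_sizes for `"modular"`: integer block sizes summing to
#'   `n_channels`. Defaults to four blocks of deliberately unequal size so the
#'   block cliques have distinct degrees.
#' @return A symmetric 0/1 adjacency matrix with zero diagonal.
#' @examples
#' coupling_topology("hub", 8)
#' coupling_topology("modular", 9, block_sizes = c(4, 3, 2))
#' @export
coupling_topology <- function(type = c("hub", "modular"), n_channels,
                              n_hubs = 2, block_sizes = NULL) {
  if (is.matrix(type)) {
    return(as_coupling_matrix(type))
  }
  type <- match.arg(type)
  stopifnot(n_channels >= 3)
  A <- matrix(0, n_channels, n_channels)
  if (type == "hub") {
    n_hubs <- max(1L, min(as.integer(n_hubs), n_channels - 1L))
    A[seq_len(n_hubs), ] <- 1
    A[, seq_len(n_hubs)] <- 1
  } else {
    if (is.null(block_sizes)) {
      block_sizes <- default_block_sizes(n_channels)
    }
    stopifnot(sum(block_sizes) == n_channels, all(block_sizes >= 1))
    stop_at <- cumsum(block_sizes)
    start_at <- c(1, head(stop_at, -1) + 1)
    for (b in seq_along(block_sizes)) {
      idx <- start_at[b]:stop_at[b]
      A[idx, idx] <- 1
    }
  }
  diag(A) <- 0
  dimnames(A) <- NULL
  A
}

# unequal block sizes ~ (35%, 30%, 20%, 15%) so clique degrees differ
default_block_sizes <- function(n) {
  frac <- c(0.35, 0.30, 0.20, 0.15)
  if (n < 8) frac <- c(0.5, 0.3, 0.2)
  sizes <- pmax(1L, round(frac * n))
  while (sum(sizes) > n) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n) sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  as.integer(sizes[sizes >= 1])
}

as_coupling_matrix <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    abort("coupling topology must be a square adjacency matrix")
  }
  if (!isTRUE(all.equal(unname(A), unname(t(A))))) {
    abort("coupling topology must be symmetric (simple undirected graph)")
  }
  if (any(A < 0)) abort("coupling weights must be non-negative")
  A <- unname(A * 1)
  diag(A) <- 0
  A
}
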