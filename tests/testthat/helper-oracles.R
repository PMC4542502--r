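# Brute-force oracles, kept deliberately independent of the implementation.

# assortativity as the Pearson correlation of end degrees, enumerating every
# link in both directions
oracle_assortativity <- function(A) {
  k <- colSums(A)
  idx <- which(A > 0, arr.ind = TRUE) # both directions
  if (nrow(idx) == 0) return(NA_real_)
  x <- k[idx[, 1]]
  y <- k[idx[, 2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# local clustering by explicit triangle enumeration over neighbour pairs
oracle_local_clustering <- function(A, n) {
  nb <- which(A[n, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  tri <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      tri <- tri + A[nb[i], nb[j]]
    }
  }
  2 * tri / (k * (k - 1))
}

oracle_mean_clustering <- function(A) {
  mean(vapply(seq_len(nrow(A)), function(n) oracle_local_clustering(A, n),
              numeric(1)))
}

# thresholding by full sort of all pairs with the (row, column) tie-break
oracle_threshold <- function(R, rho) {
  n <- nrow(R)
  pairs <- NULL
  for (col in 1:(n - 1)) {
    for (row in (col + 1):n) {
      pairs <- rbind(pairs, c(row, col, R[row, col]))
    }
  }
  L <- round(rho * n * (n - 1) / 2)
  ord <- order(-pairs[, 3], pairs[, 1], pairs[, 2])
  A <- matrix(0L, n, n)
  for (i in ord[seq_len(L)]) {
    A[pairs[i, 1], pairs[i, 2]] <- 1L
    A[pairs[i, 2], pairs[i, 1]] <- 1L
  }
  A
}

# Lomb-Scargle as an explicit least-squares sinusoid fit to the demeaned
# series: power = (RSS reduction)/2 in units of the sample variance
oracle_lomb <- function(t, y, f) {
  yd <- y - mean(y)
  X <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
  fit <- stats::lm.fit(X, yd)
  (sum(yd^2) - sum(fit$residuals^2)) / (2 * sum(yd^2) / (length(y) - 1))
}

# Erdos-Renyi-style random adjacency matrix (independent links, prob p)
random_adjacency <- function(n, p = 0.3) {
  A <- matrix(0L, n, n)
  A[lower.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# symmetric random synchrony-like matrix with distinct entries
random_sync <- function(n) {
  R <- matrix(0, n, n)
  R[lower.tri(R)] <- sample(seq_len(n * (n - 1) / 2)) / (n * n)
  R + t(R)
}
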