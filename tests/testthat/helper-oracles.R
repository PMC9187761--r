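# Shared fixtures and independent oracles.

# Six points on a line (two tight triplets), embedded in 5-D: the classic
# hand-workable k-NN / greedy-subsample fixture. Row i holds value
# line_values[i] in coordinate 1, zeros elsewhere.
line_values <- c(0, 1, 2, 10, 11, 12)
line_points <- cbind(line_values, matrix(0, 6, 4))

# Exhaustive exact k-NN oracle: Euclidean distances, ties broken towards the
# smaller index (matching the package's tie rule).
brute_knn <- function(X, k) {
  n <- nrow(X)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- d[ord]
  }
  structure(list(idx = idx, dist = dst, k = k), class = "neighbor_list")
}

# Independent 1-D W1 oracle: Riemann sum of |Fa^-1 - Fb^-1| over a fine
# uniform grid of quantile levels (midpoint rule).
w1_grid_oracle <- function(a, b, m = 2e5) {
  u <- (seq_len(m) - 0.5) / m
  qa <- sort(a)[ceiling(u * length(a))]
  qb <- sort(b)[ceiling(u * length(b))]
  mean(abs(qa - qb))
}

# Small seeded Dirichlet(1) probability vector.
rprob <- function(n) { g <- rgamma(n, 1); g / sum(g) }
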