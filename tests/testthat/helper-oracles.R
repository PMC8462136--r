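# Independent brute-force oracles used to cross-check the package's
# implementations, deliberately written with different algorithms than the
# code under test.

# Ray-casting point-in-polygon (edge-crossing count, no convexity assumption).
ray_cast_inside <- function(points, poly) {
  apply(points, 1, function(p) {
    n <- nrow(poly)
    crossings <- 0L
    for (k in seq_len(n)) {
      a <- poly[k, ]
      b <- poly[if (k == n) 1 else k + 1, ]
      if ((a[2] > p[2]) != (b[2] > p[2])) {
        x_at <- a[1] + (p[2] - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
        if (p[1] < x_at) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  })
}

# AUC by exhaustive pair enumeration: concordant + half ties over n1*n0.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Moran's I by dense double loop over an explicitly built weight matrix.
moran_dense <- function(coords, values, radius, row_standardize = TRUE) {
  n <- nrow(coords)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d <= radius) W[i, j] <- 1 / d
  }
  if (row_standardize) W <- W / rowSums(W)
  xc <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * xc[i] * xc[j]
  (n / sum(W)) * num / sum(xc^2)
}

# Autocovariate by direct double loop.
autocov_loop <- function(coords, values, radius) {
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- den <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= radius) {
        num <- num + values[j] / d
        den <- den + 1 / d
      }
    }
    out[i] <- num / den
  }
  out
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
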