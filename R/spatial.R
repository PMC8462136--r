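#' Distance-band inverse-distance spatial weights
#'
#' Neighbours of a point are all other points within `radius`; weights are the
#' inverse distances 1/d, optionally row-standardised to sum to one per focal
#' point. `radius = "auto"` uses the maximum nearest-neighbour distance, the
#' smallest band guaranteeing every point at least one neighbour.
#'
#' @param coords Two-column coordinate matrix (planar km).
#' @param radius Positive distance band, or `"auto"`.
#' @param row_standardize Divide each point's weights by their sum
#'   (default TRUE).
#' @return A `spatial_weights` object: triplet vectors `i`, `j`, `w`, plus
#'   `n`, `radius` and the distance matrix is not retained.
#' @export
build_weights <- function(coords, radius = "auto", row_standardize = TRUE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 points")
  d <- as.matrix(stats::dist(coords))
  off <- d[upper.tri(d)]
  if (any(off == 0))
    stop("duplicate coordinates (zero distance); jitter the points first")
  if (identical(radius, "auto")) {
    diag(d) <- Inf
    radius <- max(apply(d, 1, min))
    diag(d) <- 0
  }
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  sel <- which(d > 0 & d <= radius, arr.ind = TRUE)
  i <- sel[, 1]; j <- sel[, 2]
  if (length(unique(i)) < n)
    stop("some points have no neighbour within the radius; increase it")
  w <- 1 / d[sel]
  if (row_standardize) {
    rs <- vapply(split(w, i), sum, numeric(1))
    w <- w / rs[match(i, as.integer(names(rs)))]
  }
  ord <- order(i, j)
  structure(list(i = unname(i[ord]), j = unname(j[ord]), w = unname(w[ord]),
                 n = n, radius = radius,
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Spatial weights: %d points, radius %.3g, %d links%s\n",
              x$n, x$radius, length(x$w),
              if (x$row_standardized) " (row-standardised)" else ""))
  invisible(x)
}

#' Inverse-distance-weighted spatial autocovariate
#'
#' The spatial lag term used as an auxiliary SDM predictor: for each point,
#' the weighted mean of its neighbours' response values,
#' `ac_i = sum_j w_ij y_j / sum_j w_ij`. With a binary response this is the
#' weighted proportion of invaded neighbours; with frequency of occurrence it
#' is the neighbourhood mean abundance.
#'
#' @param weights A `spatial_weights` object.
#' @param response Numeric response defined at every point.
#' @return Numeric vector of length `weights$n`.
#' @export
autocovariate <- function(weights, response) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (length(response) != weights$n)
    stop("response must be defined on all points")
  num <- rowsum_vec(weights$w * response[weights$j], weights$i, weights$n)
  den <- rowsum_vec(weights$w, weights$i, weights$n)
  num / den
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Moran's I with a permutation test
#'
#' Global spatial autocorrelation
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `S0` the total weight. Significance of positive autocorrelation comes
#' from random permutations of the values over the points:
#' `p = (1 + #[I_perm >= I_obs]) / (1 + n_perm)` (one-sided).
#'
#' @param weights A `spatial_weights` object.
#' @param values Non-constant numeric vector on the points.
#' @param n_perm Number of permutations (default 999).
#' @return List with elements `I`, `p`, `expectation` (-1/(n-1)) and `n_perm`.
#' @export
morans_i <- function(weights, values, n_perm = 999) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (length(values) != weights$n) stop("values must match the weights")
  if (stats::sd(values) == 0) stop("Moran's I is undefined for constant values")
  n <- weights$n
  s0 <- sum(weights$w)
  xc <- values - mean(values)
  denom <- sum(xc^2)
  i_stat <- function(z) (n / s0) * sum(weights$w * z[weights$i] * z[weights$j]) /
    sum(z^2)
  i_obs <- (n / s0) * sum(weights$w * xc[weights$i] * xc[weights$j]) / denom
  p <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      zp <- xc[sample.int(n)]
      if (i_stat(zp) >= i_obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
  }
  list(I = i_obs, p = p, expectation = -1 / (n - 1), n_perm = n_perm)
}

#' Pair correlation function by ring counting
#'
#' Noncumulative point-pattern clustering statistic: for each distance bin
#' (an annulus of width `ring_width` centred on `r`), the number of observed
#' ordered point pairs at that separation divided by the count expected under
#' complete spatial randomness at the window's intensity. Values above 1
#' indicate clustering at that distance. No edge correction is applied; the
#' estimator is used to pick a block scale, where boundary bias is immaterial.
#'
#' @param coords Two-column coordinate matrix.
#' @param window Study window as c(width, height); pattern assumed observed on
#'   `[0, width] x [0, height]`.
#' @param r_grid Annulus centres; default 25 bins up to a quarter of the
#'   shorter window side.
#' @param ring_width Annulus width; default the grid spacing.
#' @return Data.frame with columns `r` and `g`.
#' @export
pair_correlation <- function(coords, window, r_grid = NULL, ring_width = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 points")
  if (is.null(r_grid)) {
    rmax <- min(window) / 4
    r_grid <- seq(rmax / 25, rmax, length.out = 25)
  }
  if (is.null(ring_width)) ring_width <- diff(r_grid[1:2])
  lambda <- n / prod(window)
  d <- as.numeric(stats::dist(coords))
  g <- vapply(r_grid, function(r) {
    lo <- max(0, r - ring_width / 2); hi <- r + ring_width / 2
    pairs <- 2 * sum(d >= lo & d < hi)          # ordered pairs
    expected <- n * lambda * pi * (hi^2 - lo^2) # CSR, no edge correction
    pairs / expected
  }, numeric(1))
  if (any(g == 0)) warning("empty annuli in pair correlation estimate")
  data.frame(r = r_grid, g = g)
}

#' Assign lakes to spatially blocked cross-validation folds
#'
#' Tessellates the bounding box into square blocks of side `block_side`,
#' then allocates whole blocks to folds by a randomised greedy round-robin
#' that balances per-fold lake counts, so all lakes of a block always share a
#' fold and fold sizes differ by at most the largest block occupancy.
#'
#' @param coords Two-column coordinate matrix.
#' @param block_side Block side length (km, > 0).
#' @param k_folds Number of folds (>= 2).
#' @return A `block_assignment` data.frame with columns `block` and `fold`
#'   (one row per point), with `block_side` attached as an attribute.
#' @export
assign_blocks <- function(coords, block_side, k_folds = 5) {
  coords <- as.matrix(coords)
  if (block_side <= 0) stop("block_side must be positive")
  if (k_folds < 2) stop("k_folds must be >= 2")
  bx <- floor((coords[, 1] - min(coords[, 1])) / block_side)
  by <- floor((coords[, 2] - min(coords[, 2])) / block_side)
  block <- paste(bx, by, sep = "_")
  occ <- table(block)
  if (length(occ) < k_folds)
    stop(sprintf("only %d occupied blocks for %d folds", length(occ), k_folds))
  blocks <- sample(names(occ))               # random order
  load <- numeric(k_folds)
  fold_of <- integer(length(blocks)); names(fold_of) <- blocks
  for (b in blocks) {
    f <- which.min(load)
    fold_of[b] <- f
    load[f] <- load[f] + occ[[b]]
  }
  out <- data.frame(block = block, fold = unname(fold_of[block]))
  attr(out, "block_side") <- block_side
  class(out) <- c("block_assignment", "data.frame")
  out
}
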