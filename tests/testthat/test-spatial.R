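test_that("distance-band weights match hand and brute-force computation", {
  pts <- cbind(c(0, 1, 2), c(0, 0, 0))
  w <- build_weights(pts, radius = 1.5)
  # middle point: two neighbours at distance 1, equal weight after row
  # standardisation
  mid <- w$w[w$i == 2]
  expect_equal(mid, c(0.5, 0.5))
  # auto radius equals the maximum nearest-neighbour distance
  expect_equal(build_weights(pts, "auto")$radius, 1)

  set.seed(8)
  pts50 <- cbind(runif(50, 0, 10), runif(50, 0, 10))
  w50 <- build_weights(pts50, radius = 4, row_standardize = FALSE)
  for (k in sample(length(w50$w), 25)) {
    d <- sqrt(sum((pts50[w50$i[k], ] - pts50[w50$j[k], ])^2))
    expect_equal(w50$w[k], 1 / d, tolerance = 1e-12)
  }
  expect_error(build_weights(rbind(c(0, 0), c(0, 0)), 1), "jitter")
})

test_that("autocovariate equals the weighted mean of neighbour responses", {
  pts <- cbind(c(0, 1, 2), c(0, 0, 0))
  w <- build_weights(pts, radius = 1.5)
  expect_equal(autocovariate(w, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(autocovariate(w, c(0, 7, 1))[2], 0.5)

  set.seed(12)
  pts20 <- cbind(runif(20, 0, 5), runif(20, 0, 5))
  y <- rnorm(20)
  w20 <- build_weights(pts20, radius = 3)
  expect_equal(autocovariate(w20, y), autocov_loop(pts20, y, 3),
               tolerance = 1e-12)

  # translation invariance and linearity in the response
  w_shift <- build_weights(pts20 + 100, radius = 3)
  expect_equal(autocovariate(w_shift, y), autocovariate(w20, y),
               tolerance = 1e-12)
  expect_equal(autocovariate(w20, 2 * y + 1), 2 * autocovariate(w20, y) + 1,
               tolerance = 1e-12)
})

test_that("Moran's I matches the double-sum formula and detects structure", {
  # checkerboard on a 4x4 rook grid: perfect negative autocorrelation
  grid <- expand.grid(x = 0:3, y = 0:3)
  vals <- (grid$x + grid$y) %% 2
  w <- build_weights(as.matrix(grid), radius = 1.01)
  m <- morans_i(w, vals, n_perm = 0)
  expect_lt(m$I, 0)

  # four points on a line, adjacent binary-distance weights
  line <- cbind(0:3, rep(0, 4))
  wl <- build_weights(line, radius = 1.01)
  ml <- morans_i(wl, c(1, 1, 0, 0), n_perm = 0)
  expect_equal(ml$I, moran_dense(line, c(1, 1, 0, 0), 1.01),
               tolerance = 1e-12)

  set.seed(3)
  pts <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  v <- rnorm(40)
  wp <- build_weights(pts, radius = 4)
  expect_equal(morans_i(wp, v, n_perm = 0)$I, moran_dense(pts, v, 4),
               tolerance = 1e-12)

  expect_error(morans_i(wp, rep(1, 40), n_perm = 0), "constant")
})

test_that("Moran's I cross-checks against ape's implementation", {
  skip_if_not_installed("ape")
  set.seed(5)
  pts <- cbind(runif(30, 0, 10), runif(30, 0, 10))
  v <- rnorm(30)
  w <- build_weights(pts, radius = 5, row_standardize = TRUE)
  W <- matrix(0, 30, 30)
  W[cbind(w$i, w$j)] <- w$w
  ref <- ape::Moran.I(v, W, scaled = FALSE)
  expect_equal(morans_i(w, v, n_perm = 0)$I, ref$observed, tolerance = 1e-10)
})

test_that("pair correlation is ~1 under CSR and >1 for clustered patterns", {
  set.seed(6)
  win <- c(500, 500)
  csr <- cbind(runif(2000, 0, 500), runif(2000, 0, 500))
  g_csr <- pair_correlation(csr, win)
  mid <- g_csr$r > 20 & g_csr$r < 60
  expect_lt(abs(mean(g_csr$g[mid]) - 1), 0.1)

  thomas <- simulate_thomas(2000, win, cluster_scale = 8)
  g_th <- pair_correlation(thomas, win)
  expect_gt(mean(g_th$g[g_th$r < 16]), 1)

  two <- rbind(c(0, 0), c(10, 0))
  g2 <- suppressWarnings(pair_correlation(two, c(50, 50),
                                          r_grid = seq(2, 20, by = 4),
                                          ring_width = 4))
  expect_equal(sum(g2$g > 0), 1)
})

test_that("spatial blocks tile the plane and keep blocks fold-pure", {
  set.seed(7)
  # two well-separated clusters with one large block each
  cl <- rbind(cbind(rnorm(30, 10, 1), rnorm(30, 10, 1)),
              cbind(rnorm(30, 90, 1), rnorm(30, 90, 1)))
  ba <- assign_blocks(cl, block_side = 20, k_folds = 2)
  expect_equal(length(unique(ba$fold[1:30])), 1)
  expect_equal(length(unique(ba$fold[31:60])), 1)
  expect_false(ba$fold[1] == ba$fold[31])

  pts <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  ba2 <- assign_blocks(pts, block_side = 10, k_folds = 5)
  expect_equal(nrow(ba2), 300)
  expect_setequal(unique(ba2$fold), 1:5)
  # within-block fold homogeneity
  expect_true(all(tapply(ba2$fold, ba2$block, function(f)
    length(unique(f))) == 1))
  # fold sizes differ by at most the largest block occupancy
  sizes <- table(ba2$fold)
  expect_lte(max(sizes) - min(sizes), max(table(ba2$block)))

  expect_error(assign_blocks(pts, block_side = 1000, k_folds = 2),
               "occupied blocks")
})
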