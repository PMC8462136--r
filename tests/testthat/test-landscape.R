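test_that("a fixed seed reproduces the landscape byte for byte", {
  cfg <- simulation_config(seed = 42)
  t1 <- generate_landscape(cfg)
  t2 <- generate_landscape(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_lake_table(t1, f1)
  write_lake_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the default recipe reproduces the study's lake counts", {
  t <- generate_landscape(simulation_config(seed = 1))
  expect_equal(sum(t$surveyed & t$presence == 1), 184)
  expect_equal(sum(t$surveyed & t$presence == 0), 284)
  expect_equal(sum(!t$surveyed), 801)
  expect_equal(nrow(t), 1269)
  # count conservation and response invariants
  expect_true(all(is.na(t$presence[!t$surveyed])))
  sv <- t[t$surveyed, ]
  expect_true(all(sv$freq_occ[sv$presence == 0] == 0))
  expect_true(all(sv$freq_occ[sv$presence == 1] > 0))
})

test_that("config validation rejects inconsistent recipes", {
  expect_error(simulation_config(n_presence = 0), "positive")
  cs <- default_covariate_spec()
  cs$mean[1] <- cs$max[1] + 1
  expect_error(simulation_config(covariate_spec = cs), "min <= mean <= max")
  expect_error(
    simulation_config(suitability_params = list(
      plateaus = c(gdd_wtr_10c = 5000, lake_depth = 30, road_density = 75),
      weights = c(gdd_wtr_10c = 1, lake_depth = 1, road_density = 1),
      intercept = 0)),
    "plateau")
})

test_that("an unrealisable presence count fails naming the budget", {
  sp <- list(plateaus = c(gdd_wtr_10c = 1750, lake_depth = 30,
                          road_density = 75),
             weights = c(gdd_wtr_10c = 1, lake_depth = 1, road_density = 1),
             intercept = -30)  # suitability ~ 0 everywhere
  expect_error(
    generate_landscape(simulation_config(seed = 1, suitability_params = sp,
                                         resample_budget = 3)),
    "budget")
})

test_that("point-intercept sampling is binomial with the right moments", {
  expect_error(simulate_point_intercept(1.2, 10), "0, 1")
  expect_error(simulate_point_intercept(0.5, 0), "n_points")
  set.seed(1)
  expect_equal(simulate_point_intercept(rep(0, 25), 40), rep(0, 25))
  expect_equal(simulate_point_intercept(rep(1, 25), 50), rep(1, 25))
  reps <- simulate_point_intercept(rep(0.3, 10000), 100)
  se <- sqrt(0.3 * 0.7 / 100) / sqrt(10000)
  expect_lt(abs(mean(reps) - 0.3), 3 * se)
})

test_that("abundance is zero without suitable habitat and wedge-shaped with it", {
  # no presences when suitability is zero everywhere -> all freq_occ zero
  t <- unit_square_table(cbind(2, 2))
  t$presence[t$surveyed] <- 0L
  t$freq_occ[t$surveyed] <- NA_real_
  t$s_true <- 0
  cfg <- simulation_config(seed = 3)
  set.seed(1)
  out <- assign_abundance(t, cfg)
  expect_true(all(out$freq_occ[out$surveyed] == 0))

  # default landscape: right-skewed nonzero abundance, bounded near 0.8
  l <- generate_landscape(simulation_config(seed = 7))
  nz <- l$freq_occ[l$surveyed & l$presence == 1]
  expect_gt(sample_skewness(nz), 0)
  expect_lte(max(nz), 0.8 + 3 * sqrt(0.8 * 0.2 / 100))
})

test_that("covariates are spatially autocorrelated over the lakes", {
  l <- generate_landscape(simulation_config(seed = 2))
  w <- build_weights(cbind(l$x, l$y), "auto")
  set.seed(9)
  for (v in c("gdd_wtr_10c", "lake_depth", "secchi_depth")) {
    m <- morans_i(w, l[[v]], n_perm = 99)
    expect_gt(m$I, 0)
    expect_lte(m$p, 0.05)
  }
})

test_that("lake tables round-trip through CSV", {
  l <- generate_landscape(small_config(seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_lake_table(l, f)
  header <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_identical(header[1:6],
                   c("id", "x", "y", "surveyed", "presence", "freq_occ"))
  expect_false("s_true" %in% header)
  back <- read_lake_table(f)
  expect_equal(back$freq_occ, l$freq_occ)
  expect_equal(back$gdd_wtr_10c, l$gdd_wtr_10c, tolerance = 1e-12)
  expect_true(all(is.na(back$presence[!back$surveyed])))
})

test_that("thomas patterns are clustered relative to uniform ones", {
  set.seed(4)
  extent <- c(400, 400)
  pts <- simulate_thomas(1500, extent, cluster_scale = 10)
  g <- pair_correlation(pts, extent)
  expect_gt(mean(g$g[g$r < 20]), 1.2)
})
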