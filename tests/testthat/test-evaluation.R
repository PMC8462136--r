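test_that("AUC matches exhaustive pair counting and is rank-invariant", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  set.seed(1)
  for (rep in 1:5) {
    s <- sample(seq(0, 1, by = 0.1), 10, replace = TRUE)  # with ties
    l <- sample(c(0, 1), 10, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), auc_pairs(s, l), tolerance = 1e-12)
    # strictly monotone transform leaves AUC unchanged
    expect_equal(roc_auc(exp(3 * s), l), roc_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("the equality threshold balances sensitivity and specificity", {
  expect_equal(equality_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)
  cc <- confusion_counts(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5)
  expect_equal(tss(cc), 1)

  set.seed(2)
  s <- c(rnorm(1000, 0), rnorm(1000, 1))
  l <- rep(c(0, 1), each = 1000)
  thr <- equality_threshold(s, l)
  cc2 <- confusion_counts(s, l, thr)
  sens <- cc2$tp / (cc2$tp + cc2$fn)
  spec <- cc2$tn / (cc2$tn + cc2$fp)
  expect_lt(abs(sens - spec), 0.05)

  # deterministic under label reversal
  expect_identical(equality_threshold(s, l), equality_threshold(s, l))
  expect_type(equality_threshold(s, 1 - l), "double")
})

test_that("TSS and kappa follow their contingency formulas", {
  cc <- list(tp = 90, fn = 10, tn = 80, fp = 20)
  expect_equal(tss(cc), 0.9 + 0.8 - 1, tolerance = 1e-12)
  cc2 <- list(tp = 40, tn = 40, fp = 10, fn = 10)
  expect_equal(cohen_kappa(cc2), 0.6, tolerance = 1e-12)
  expect_error(tss(list(tp = 0, fn = 0, tn = 5, fp = 5)), "TSS")
  # random predictions at large n: both statistics near zero
  set.seed(3)
  lab <- rbinom(4000, 1, 0.5)
  prd <- rbinom(4000, 1, 0.5)
  cc3 <- list(tp = sum(prd & lab), fp = sum(prd & !lab),
              fn = sum(!prd & lab), tn = sum(!prd & !lab))
  se <- 2 / sqrt(4000)
  expect_lt(abs(tss(cc3)), 2 * se)
  expect_lt(abs(cohen_kappa(cc3)), 2 * se)
})

test_that("all three evaluation schemes ace a separable dataset", {
  ds <- separable_dataset(n = 150, n_noise = 2)
  for (sch in c("nonindependent", "quasi_independent", "spatially_blocked")) {
    m <- evaluate_discrimination(ds, sch, n_iter = 1, ntree = 100,
                                 block_side = 25, seed = 4)
    expect_gte(m$auc, 0.99)
    expect_gte(m$tss, 0.8)
  }
})

test_that("evaluation is reproducible under a fixed seed", {
  ds <- separable_dataset(n = 120, n_noise = 2)
  m1 <- evaluate_discrimination(ds, "nonindependent", n_iter = 1, ntree = 80,
                                seed = 6)
  m2 <- evaluate_discrimination(ds, "nonindependent", n_iter = 1, ntree = 80,
                                seed = 6)
  expect_identical(m1[c("auc", "tss", "kappa")], m2[c("auc", "tss", "kappa")])
  expect_error(evaluate_discrimination(
    make_dataset(data.frame(a = rnorm(20)), rep(1, 20)), "nonindependent"),
    "single class")
})

test_that("functional accuracy behaves on exact, monotone and null inputs", {
  fo <- c(0, 0, 0.1, 0.3, 0.5, 0.7, 0.2, 0, 0.4, 0.6)
  exact <- functional_accuracy(fo, fo)
  expect_equal(exact$r_all, 1)
  expect_equal(exact$rho_nonzero, 1)

  mono <- functional_accuracy(fo^3, fo)   # monotone transform
  expect_equal(mono$rho_all, 1)
  expect_lt(mono$r_all, 1)

  set.seed(7)
  null <- functional_accuracy(runif(468), c(rep(0, 284), runif(184, 0, 0.8)))
  expect_lt(abs(null$r_all), 0.1)
  expect_lt(abs(null$rho_nonzero), 0.2)

  few <- functional_accuracy(c(0.5, 0.2, 0.9, 0.1), c(0, 0, 0.3, 0))
  expect_true(is.na(few$r_nonzero))
})

test_that("quantile lines recover exact fits and beat least squares on check loss", {
  x <- seq(0.01, 1, length.out = 50)
  for (tau in c(0.5, 0.75, 0.9)) {
    f <- quantile_line(x, 0.5 * x, tau)
    expect_equal(f$slope, 0.5, tolerance = 1e-6)
    expect_lt(abs(f$intercept), 1e-6)
  }
  set.seed(8)
  xr <- runif(300)
  yr <- 0.3 * xr + rexp(300, 10)   # asymmetric noise
  ols <- stats::coef(stats::lm(yr ~ xr))
  for (tau in c(0.5, 0.75, 0.9)) {
    f <- quantile_line(xr, yr, tau)
    loss_fit <- sum((yr - f$intercept - f$slope * xr) *
                      (tau - ((yr - f$intercept - f$slope * xr) < 0)))
    loss_ols <- sum((yr - ols[1] - ols[2] * xr) *
                      (tau - ((yr - ols[1] - ols[2] * xr) < 0)))
    expect_lte(loss_fit, loss_ols + 1e-9)
  }
  expect_error(quantile_line(rep(1, 30), rnorm(30), 0.5), "degenerate")
})

test_that("the wedge fit recovers closed-form quantile slopes of y ~ U(0, x)", {
  set.seed(9)
  x <- runif(2000)
  y <- runif(2000, 0, x)
  w <- wedge_quantiles(x, y)
  expect_equal(w$slope[w$tau == 0.50], 0.50, tolerance = 0.05)
  expect_equal(w$slope[w$tau == 0.75], 0.75, tolerance = 0.05)
  expect_equal(w$slope[w$tau == 0.90], 0.90, tolerance = 0.05)
  expect_gt(attr(w, "wedge_strength"), 0)
  expect_error(wedge_quantiles(1:10, 1:10), "20 pairs")
})
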