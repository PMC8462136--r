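# Shared fixtures built in code at test time.

# A reduced landscape for pipeline-level tests: same spatial structure as the
# default recipe, fewer lakes so forests fit in milliseconds.
small_config <- function(seed = 11, ...) {
  simulation_config(n_presence = 60, n_absence = 80, n_unsurveyed = 300,
                    seed = seed, ...)
}

# A hand-built minimal lake table: presences on the unit square, plus
# surveyed absences and unsurveyed candidates at known positions.
unit_square_table <- function(candidates) {
  pres <- data.frame(x = c(0, 0, 1, 1), y = c(0, 1, 1, 0))
  abs_ <- data.frame(x = c(0.2, 0.4), y = c(0.3, 0.9))
  n <- nrow(pres) + nrow(abs_) + nrow(candidates)
  df <- data.frame(
    id = sprintf("L%02d", seq_len(n)),
    x = c(pres$x, abs_$x, candidates[, 1]),
    y = c(pres$y, abs_$y, candidates[, 2]),
    surveyed = c(rep(TRUE, 6), rep(FALSE, nrow(candidates))),
    presence = c(1L, 1L, 1L, 1L, 0L, 0L, rep(NA_integer_, nrow(candidates))),
    freq_occ = c(0.5, 0.4, 0.3, 0.2, 0, 0, rep(NA_real_, nrow(candidates))),
    cov_a = seq_len(n) / n,
    cov_b = rev(seq_len(n)) / n
  )
  class(df) <- c("lake_table", "data.frame")
  df
}

# A linearly separable occurrence dataset: label decided by one covariate
# threshold, remaining covariates pure noise.
separable_dataset <- function(n = 200, n_noise = 4, seed = 5) {
  set.seed(seed)
  x1 <- runif(n)
  label <- as.integer(x1 > 0.5)
  feats <- data.frame(x1 = x1)
  for (k in seq_len(n_noise)) feats[[paste0("noise", k)]] <- rnorm(n)
  make_dataset(feats, label)
}

# Assemble a response_dataset directly from features and labels.
make_dataset <- function(features, label, coords = NULL, kind = "PA") {
  n <- nrow(features)
  if (is.null(coords))
    coords <- cbind(x = runif(n, 0, 100), y = runif(n, 0, 100))
  structure(list(kind = kind, ids = sprintf("s%04d", seq_len(n)),
                 label = label,
                 role = ifelse(label == 1, "presence", "absence"),
                 coords = coords, features = features, has_autocov = FALSE),
            class = "response_dataset")
}
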