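## Shared random-forest fitting helper. Occurrence kinds get a classification
## forest (suitability = fraction of trees voting presence), ABUNDANCE a
## regression forest. Hyperparameters follow the randomForest defaults:
## sqrt(p) / p/3 features per split, unlimited depth.
rf_fit <- function(features, label, kind, ntree = 500, mtry = NULL) {
  occurrence <- kind != "ABUNDANCE"
  if (occurrence) {
    y <- factor(label, levels = c(0, 1))
    if (length(unique(label)) < 2)
      stop("training labels are single-class; cannot fit an occurrence SDM")
  } else {
    y <- label
  }
  if (is.null(mtry))
    mtry <- if (occurrence) max(1, floor(sqrt(ncol(features))))
      else max(1, floor(ncol(features) / 3))
  randomForest::randomForest(x = features, y = y, ntree = ntree, mtry = mtry)
}

rf_suitability <- function(forest, features) {
  if (forest$type == "classification") {
    unname(stats::predict(forest, features, type = "prob")[, "1"])
  } else {
    unname(stats::predict(forest, features))
  }
}

## Out-of-bag suitability on the forest's own training rows: honest
## predictions without refitting.
rf_oob <- function(forest) {
  if (forest$type == "classification") unname(forest$votes[, "1"])
  else unname(forest$predicted)
}

stratified_split <- function(label, train_frac, stratify) {
  n <- length(label)
  if (stratify) {
    train <- unlist(lapply(split(seq_len(n), label), function(idx) {
      sample(idx, round(length(idx) * train_frac))
    }), use.names = FALSE)
  } else {
    train <- sample.int(n, round(n * train_frac))
  }
  sort(train)
}

stratified_folds <- function(label, k) {
  n <- length(label)
  fold <- integer(n)
  for (idx in split(seq_len(n), label)) {
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit a random-forest SDM to a response dataset
#'
#' Occurrence datasets (PA and the three presence-only kinds) are fitted with
#' a classification forest whose vote fraction is the predicted suitability;
#' the ABUNDANCE dataset gets a regression forest predicting frequency of
#' occurrence. The dataset is split 70/30 into training and test rows
#' (stratified by class for occurrence kinds) and the forest is fitted on the
#' training rows; `split = 1` fits on all rows, the variant used for final
#' full-data suitability maps.
#'
#' @param dataset A `response_dataset`.
#' @param include_autocov Use the `autocov` feature column? Defaults to
#'   whatever the dataset carries; `FALSE` drops it, `TRUE` requires it.
#' @param split Training fraction (default 0.7).
#' @param ntree,mtry Forest size and features per split (NULL = randomForest
#'   default).
#' @param seed Optional integer; set for reproducible splits and forests.
#' @return A `fitted_sdm`: the forest, the dataset, train/test row indices,
#'   and out-of-bag training predictions.
#' @export
fit_sdm <- function(dataset, include_autocov = dataset$has_autocov,
                    split = 0.7, ntree = 500, mtry = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "response_dataset"))
  if (!is.null(seed)) set.seed(seed)
  features <- dataset$features
  if (include_autocov && !("autocov" %in% names(features)))
    stop("dataset has no autocovariate column; call add_autocovariate() first")
  if (!include_autocov) features$autocov <- NULL
  occurrence <- dataset$kind != "ABUNDANCE"
  train <- if (split >= 1) seq_along(dataset$ids)
    else stratified_split(dataset$label, split, stratify = occurrence)
  test <- setdiff(seq_along(dataset$ids), train)
  forest <- rf_fit(features[train, , drop = FALSE], dataset$label[train],
                   dataset$kind, ntree = ntree, mtry = mtry)
  structure(list(kind = dataset$kind, includes_autocov = include_autocov,
                 forest = forest, dataset = dataset, features = features,
                 train = train, test = test, oob = rf_oob(forest),
                 ntree = ntree, seed = seed),
            class = "fitted_sdm")
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("Random-forest SDM [%s]%s: %d training / %d test lakes, %d trees\n",
              x$kind, if (x$includes_autocov) " + autocovariate" else "",
              length(x$train), length(x$test), x$ntree))
  invisible(x)
}

#' Predict suitability (or frequency of occurrence) from a fitted SDM
#'
#' @param object A `fitted_sdm`.
#' @param newdata Feature data.frame with the model's columns; defaults to the
#'   model's own feature table.
#' @param ... Unused.
#' @return Predictions in [0, 1]: vote-fraction suitability for occurrence
#'   models, leaf-average frequency of occurrence for abundance models.
#' @export
predict.fitted_sdm <- function(object, newdata = object$features, ...) {
  rf_suitability(object$forest, newdata[, rownames(object$forest$importance),
                                        drop = FALSE])
}

#' Permutation importance on held-out data
#'
#' Relative variable importance as the percent increase in mean-squared error
#' when a feature column is permuted:
#' `100 * (MSE_permuted - MSE_base) / MSE_base`, averaged over `n_repeats`
#' permutations, computed on the model's held-out test rows. Occurrence
#' models use the Brier-style MSE of predicted suitability against the 0/1
#' label.
#'
#' @param model A `fitted_sdm` with a nonempty test partition.
#' @param n_repeats Permutations per feature (default 10).
#' @return An `importance_table` data.frame: `covariate`, `importance`
#'   (percent change in MSE), `rank` (1 = most important).
#' @export
permutation_importance <- function(model, n_repeats = 10) {
  stopifnot(inherits(model, "fitted_sdm"))
  if (length(model$test) == 0)
    stop("model has no held-out rows; fit with split < 1")
  feats <- model$features[model$test, , drop = FALSE]
  y <- model$dataset$label[model$test]
  base <- mean((predict(model, feats) - y)^2)
  imp <- vapply(names(feats), function(v) {
    mean(vapply(seq_len(n_repeats), function(r) {
      perm <- feats
      perm[[v]] <- sample(perm[[v]])
      mean((predict(model, perm) - y)^2)
    }, numeric(1)))
  }, numeric(1))
  pct <- 100 * (imp - base) / base
  out <- data.frame(covariate = names(feats), importance = unname(pct))
  out$rank <- rank(-out$importance, ties.method = "first")
  class(out) <- c("importance_table", "data.frame")
  out[order(out$rank), ]
}

#' Partial dependence of a fitted SDM on one covariate
#'
#' Standard all-rows substitution: the covariate is set to each of
#' `grid_size` values spanning its observed range while every other feature
#' keeps its actual values, and predictions are averaged.
#'
#' @param model A `fitted_sdm`.
#' @param covariate Feature name.
#' @param grid_size Number of grid points (default 50).
#' @return A `partial_dependence` data.frame with columns `covariate`,
#'   `value`, `response`.
#' @export
partial_dependence <- function(model, covariate, grid_size = 50) {
  stopifnot(inherits(model, "fitted_sdm"))
  feats <- model$features[model$train, , drop = FALSE]
  if (!covariate %in% names(feats))
    stop("unknown covariate: ", covariate)
  grid <- seq(min(feats[[covariate]]), max(feats[[covariate]]),
              length.out = grid_size)
  response <- vapply(grid, function(g) {
    sub <- feats
    sub[[covariate]] <- g
    mean(predict(model, sub))
  }, numeric(1))
  out <- data.frame(covariate = covariate, value = grid, response = response)
  class(out) <- c("partial_dependence", "data.frame")
  out
}

#' Suitability predictions for every surveyed lake
#'
#' The per-lake predictions used by functional accuracy and the wedge plots:
#' out-of-bag votes for lakes that are in the model's training data (in-sample
#' forest predictions are degenerate), ordinary predictions for surveyed lakes
#' the model never saw (e.g. true absences under a presence-only model). For
#' models carrying an autocovariate, lakes outside the model's dataset get
#' their spatial lag computed against the dataset's lakes and responses.
#'
#' @param model A `fitted_sdm`.
#' @param table The `lake_table` the model's dataset was built from.
#' @return Named numeric vector of suitability over surveyed lakes (names =
#'   lake ids); NA for lakes whose covariates are incomplete.
#' @export
sdm_suitability <- function(model, table) {
  stopifnot(inherits(model, "fitted_sdm"))
  sv <- table[table$surveyed, ]
  pred <- numeric(nrow(sv))
  names(pred) <- sv$id
  in_train <- match(sv$id, model$dataset$ids[model$train])
  seen <- !is.na(in_train)
  pred[seen] <- model$oob[in_train[seen]]
  if (any(!seen)) {
    unseen <- sv[!seen, ]
    feats <- unseen[, lake_covariate_names(table), drop = FALSE]
    if (model$includes_autocov) {
      feats$autocov <- lag_against(cbind(unseen$x, unseen$y),
                                   model$dataset$coords,
                                   model$dataset$label,
                                   radius = model$dataset$autocov_radius)
    }
    complete <- stats::complete.cases(feats)
    vals <- rep(NA_real_, nrow(feats))
    if (any(complete))
      vals[complete] <- predict(model, feats[complete, , drop = FALSE])
    pred[!seen] <- vals
  }
  pred
}

## Inverse-distance-weighted mean of ref_response at reference points within
## `radius` of each new point; falls back to the nearest reference point when
## the band is empty. Zero-distance pairs (a new point coinciding with a
## reference lake) are excluded as self-neighbours.
lag_against <- function(new_coords, ref_coords, ref_response, radius = NULL) {
  d <- sqrt(outer(new_coords[, 1], ref_coords[, 1], "-")^2 +
              outer(new_coords[, 2], ref_coords[, 2], "-")^2)
  d[d < 1e-9] <- Inf
  if (is.null(radius)) radius <- max(apply(d, 1, min))
  vapply(seq_len(nrow(d)), function(i) {
    nb <- which(d[i, ] <= radius)
    if (length(nb) == 0) nb <- which.min(d[i, ])
    w <- 1 / d[i, nb]
    sum(w * ref_response[nb]) / sum(w)
  }, numeric(1))
}
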