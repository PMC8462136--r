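#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midrank tie correction: the probability that a random presence scores
#' higher than a random (pseudo)absence, ties counting one half.
#'
#' @param scores Numeric predicted suitabilities.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a threshold
#'
#' Presence is predicted when `score >= threshold`.
#'
#' @param scores,labels Predictions and 0/1 labels.
#' @param threshold Classification cutoff.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  structure(list(tp = sum(pred == 1 & labels == 1),
                 fp = sum(pred == 1 & labels == 0),
                 fn = sum(pred == 0 & labels == 1),
                 tn = sum(pred == 0 & labels == 0)),
            class = "confusion_counts")
}

#' Sensitivity-specificity equality threshold
#'
#' The preferred thresholding rule when presences and absences should have
#' equal chances of correct prediction: among candidate cutoffs (midpoints of
#' consecutive sorted unique scores, plus guards below and above all scores),
#' returns the one minimising `|sensitivity - specificity|`; ties are broken
#' by larger `sensitivity + specificity`, then by the lower threshold.
#'
#' @param scores,labels Predictions and 0/1 labels (both classes present).
#' @return The selected threshold.
#' @export
equality_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("threshold needs both classes present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  sens <- vapply(cand, function(t) sum(scores >= t & labels == 1) / n1,
                 numeric(1))
  spec <- vapply(cand, function(t) sum(scores < t & labels == 0) / n0,
                 numeric(1))
  ord <- order(abs(sens - spec), -(sens + spec), cand)
  cand[ord[1]]
}

#' True skill statistic and Cohen's kappa from confusion counts
#'
#' `tss = sensitivity + specificity - 1`. Kappa is the chance-corrected
#' agreement `(p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' row/column margins.
#'
#' @param counts A `confusion_counts` object (or list with tp/fp/fn/tn).
#' @return A real in [-1, 1].
#' @export
tss <- function(counts) {
  with(counts, {
    if (tp + fn == 0 || tn + fp == 0)
      stop("TSS undefined: a true class is empty")
    tp / (tp + fn) + tn / (tn + fp) - 1
  })
}

#' @rdname tss
#' @export
cohen_kappa <- function(counts) {
  with(counts, {
    n <- tp + fp + fn + tn
    p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
    if (p_e == 1)
      stop("kappa undefined: degenerate margins (all predictions and labels agree on one class)")
    p_o <- (tp + tn) / n
    (p_o - p_e) / (1 - p_e)
  })
}

## Metrics for one train/test fold: forest on the training rows, threshold
## from the training out-of-bag suitabilities, AUC/TSS/Kappa on the held-out
## rows. Returns NULL when the held-out fold is single-class.
fold_metrics <- function(features, label, kind, train, test, ntree, mtry) {
  if (length(unique(label[test])) < 2 || length(unique(label[train])) < 2)
    return(NULL)
  forest <- rf_fit(features[train, , drop = FALSE], label[train], kind,
                   ntree = ntree, mtry = mtry)
  thr <- equality_threshold(rf_oob(forest), label[train])
  p <- rf_suitability(forest, features[test, , drop = FALSE])
  cc <- confusion_counts(p, label[test], thr)
  kp <- tryCatch(cohen_kappa(cc), error = function(e) NA_real_)
  c(auc = roc_auc(p, label[test]), tss = tss(cc), kappa = kp, threshold = thr)
}

#' Discrimination accuracy under one of three evaluation schemes
#'
#' Computes AUC, TSS and Kappa for an occurrence dataset under:
#' \describe{
#'   \item{nonindependent}{random 5-fold cross-validation repeated
#'     `n_iter` times (50 by default); reported metrics are the mean over all
#'     fold-level estimates.}
#'   \item{quasi_independent}{a single stratified 70/30 train/test split.}
#'   \item{spatially_blocked}{cross-validation whose folds are contiguous
#'     square blocks of side `block_side` from [assign_blocks()]; metrics are
#'     averaged over folds.}
#' }
#' Thresholds for TSS/Kappa are refit within each training fold using the
#' sensitivity-specificity equality rule on out-of-bag predictions. Folds
#' whose held-out part is single-class are skipped with a warning; if at
#' least half the folds are skipped the evaluation fails.
#'
#' @param dataset A `response_dataset` of an occurrence kind (binary labels,
#'   both classes present). If it carries an autocovariate column, that
#'   column is used as a predictor (it was computed on the full dataset; see
#'   [add_autocovariate()]).
#' @param scheme Evaluation scheme.
#' @param n_folds,n_iter Fold count and repetitions for the nonindependent
#'   scheme.
#' @param block_side Block side (landscape units) for the spatially blocked
#'   scheme; the package-wide defaults are 10 for occurrence models and 5 for
#'   proximal presence-only models.
#' @param k_folds_blocked Number of spatial folds (default 5).
#' @param train_frac Training fraction for the quasi-independent split.
#' @param ntree,mtry Forest hyperparameters.
#' @param seed Optional seed for reproducibility.
#' @return A `discrimination_metrics` list: `scheme`, `auc`, `tss`, `kappa`,
#'   `threshold` (mean over folds), `n_folds_used`, `n_folds_skipped`.
#' @export
evaluate_discrimination <- function(dataset,
                                    scheme = c("nonindependent",
                                               "quasi_independent",
                                               "spatially_blocked"),
                                    n_folds = 5, n_iter = 50,
                                    block_side = 10, k_folds_blocked = 5,
                                    train_frac = 0.7,
                                    ntree = 500, mtry = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "response_dataset"))
  if (dataset$kind == "ABUNDANCE")
    stop("discrimination accuracy applies to occurrence datasets only")
  if (length(unique(dataset$label)) < 2) stop("dataset has a single class")
  if (!is.null(seed)) set.seed(seed)
  features <- dataset$features
  label <- dataset$label

  folds <- switch(scheme,
    nonindependent = {
      unlist(lapply(seq_len(n_iter), function(it) {
        f <- stratified_folds(label, n_folds)
        lapply(seq_len(n_folds), function(k) which(f == k))
      }), recursive = FALSE)
    },
    quasi_independent = {
      train <- stratified_split(label, train_frac, stratify = TRUE)
      list(setdiff(seq_along(label), train))
    },
    spatially_blocked = {
      ba <- assign_blocks(dataset$coords, block_side, k_folds_blocked)
      lapply(seq_len(k_folds_blocked), function(k) which(ba$fold == k))
    })

  rows <- lapply(folds, function(test) {
    m <- fold_metrics(features, label, dataset$kind,
                      setdiff(seq_along(label), test), test,
                      ntree = ntree, mtry = mtry)
    if (is.null(m)) warning("skipped a single-class fold")
    m
  })
  used <- Filter(Negate(is.null), rows)
  if (length(used) * 2 < length(folds))
    stop("more than half of the evaluation folds were single-class")
  m <- colMeans(do.call(rbind, used), na.rm = TRUE)
  structure(list(scheme = scheme, auc = m[["auc"]], tss = m[["tss"]],
                 kappa = m[["kappa"]], threshold = m[["threshold"]],
                 n_folds_used = length(used),
                 n_folds_skipped = length(folds) - length(used)),
            class = "discrimination_metrics")
}

#' @export
print.discrimination_metrics <- function(x, ...) {
  cat(sprintf("%s evaluation: AUC %.3f, TSS %.3f, Kappa %.3f (threshold %.3f, %d folds)\n",
              x$scheme, x$auc, x$tss, x$kappa, x$threshold, x$n_folds_used))
  invisible(x)
}

#' Functional accuracy: abundance-suitability correlations
#'
#' Pearson and Spearman correlations between predicted suitability and
#' observed frequency of occurrence over surveyed lakes, reported both
#' including zero-abundance lakes (`r_all`, `rho_all`) and excluding them
#' (`r_nonzero`, `rho_nonzero`) -- zeros reward mere discrimination and can
#' inflate the correlation, so the nonzero variants isolate how well
#' suitability tracks abundance where the species occurs.
#'
#' @param predictions Suitability per surveyed lake (e.g. from
#'   [sdm_suitability()]).
#' @param freq_occ Observed frequency of occurrence, same length/order.
#' @return A `functional_metrics` list with `r_all`, `r_nonzero`, `rho_all`,
#'   `rho_nonzero`; the nonzero pair is NA when fewer than 3 lakes have
#'   positive abundance.
#' @export
functional_accuracy <- function(predictions, freq_occ) {
  ok <- !is.na(predictions) & !is.na(freq_occ)
  predictions <- predictions[ok]; freq_occ <- freq_occ[ok]
  if (length(freq_occ) < 3) stop("need at least 3 lakes")
  nz <- freq_occ > 0
  out <- list(
    r_all = stats::cor(predictions, freq_occ),
    r_nonzero = if (sum(nz) >= 3) stats::cor(predictions[nz], freq_occ[nz])
      else NA_real_,
    rho_all = stats::cor(predictions, freq_occ, method = "spearman"),
    rho_nonzero = if (sum(nz) >= 3)
      stats::cor(predictions[nz], freq_occ[nz], method = "spearman")
      else NA_real_)
  class(out) <- "functional_metrics"
  out
}

#' @export
print.functional_metrics <- function(x, ...) {
  cat(sprintf("Functional accuracy: r_all %.3f, r_nonzero %.3f, rho_all %.3f, rho_nonzero %.3f\n",
              x$r_all, x$r_nonzero, x$rho_all, x$rho_nonzero))
  invisible(x)
}

check_loss <- function(res, tau) sum(res * (tau - (res < 0)))

#' Linear quantile regression of y on x
#'
#' Minimises the check (pinball) loss
#' `sum_i rho_tau(y_i - b0 - b1 x_i)` for a single predictor. The fit starts
#' from the least-squares line, runs iteratively reweighted least squares on
#' a smoothed check loss, polishes with Nelder-Mead on the exact loss, and
#' returns whichever candidate achieves the lowest exact check loss -- so the
#' result never does worse than the least-squares line at that quantile.
#'
#' @param x,y Numeric vectors.
#' @param tau Quantile level in (0, 1).
#' @return List with `intercept`, `slope`, `tau`, `loss`.
#' @export
quantile_line <- function(x, y, tau) {
  stopifnot(tau > 0, tau < 1, length(x) == length(y))
  if (stats::sd(x) == 0) stop("degenerate predictor: zero variance")
  ls <- stats::coef(stats::lm.fit(cbind(1, x), y))
  b <- ls
  eps <- 1e-6
  for (it in 1:60) {
    r <- y - b[1] - b[2] * x
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    b_new <- stats::coef(stats::lm.wfit(cbind(1, x), y, w))
    if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
    b <- b_new
  }
  obj <- function(p) check_loss(y - p[1] - p[2] * x, tau)
  nm <- stats::optim(b, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 2000))
  cands <- list(ls, b, nm$par)
  losses <- vapply(cands, obj, numeric(1))
  best <- cands[[which.min(losses)]]
  list(intercept = unname(best[1]), slope = unname(best[2]), tau = tau,
       loss = min(losses))
}

#' Quantile-regression wedge of the abundance-suitability relationship
#'
#' Fits linear quantile regressions of frequency of occurrence on predicted
#' suitability at the 50th, 75th and 90th percentiles. In a wedge-shaped
#' relationship -- suitability bounds abundance from above without
#' determining it -- the upper-quantile slopes exceed the median slope;
#' `wedge_strength`, the 90th-minus-50th slope difference, measures how
#' pronounced the wedge is.
#'
#' @param suitability Predicted suitability (>= 20 values).
#' @param freq_occ Observed frequency of occurrence.
#' @param taus Quantile levels (fixed default 0.50, 0.75, 0.90).
#' @return A `wedge_fit` data.frame (`tau`, `slope`, `intercept`) with a
#'   `wedge_strength` attribute.
#' @export
wedge_quantiles <- function(suitability, freq_occ,
                            taus = c(0.50, 0.75, 0.90)) {
  ok <- !is.na(suitability) & !is.na(freq_occ)
  suitability <- suitability[ok]; freq_occ <- freq_occ[ok]
  if (length(suitability) < 20) stop("need at least 20 pairs")
  fits <- lapply(taus, function(t) quantile_line(suitability, freq_occ, t))
  out <- data.frame(tau = taus,
                    slope = vapply(fits, `[[`, numeric(1), "slope"),
                    intercept = vapply(fits, `[[`, numeric(1), "intercept"))
  attr(out, "wedge_strength") <-
    out$slope[out$tau == 0.90] - out$slope[out$tau == 0.50]
  class(out) <- c("wedge_fit", "data.frame")
  out
}

#' @export
print.wedge_fit <- function(x, ...) {
  cat("Quantile-regression wedge:\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  cat(sprintf("wedge strength (slope_90 - slope_50): %.3f\n",
              attr(x, "wedge_strength")))
  invisible(x)
}
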