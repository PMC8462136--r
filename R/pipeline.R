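#' Configuration of a full modelling experiment
#'
#' Bundles everything [run_experiment()] needs: where the lake table comes
#' from (a simulated landscape or a CSV), how pseudoabsences are drawn, the
#' autocovariate radius, cross-validation settings and spatial block sides,
#' and the forest size. Defaults follow the study design: 284 pseudoabsences
#' per presence-only dataset, 5-fold nonindependent CV with 50 iterations,
#' block side 10 (landscape units) for occurrence models and 5 for proximal
#' presence-only models, 500 trees.
#'
#' @param simulation A `simulation_config`, used when `input_csv` is NULL.
#' @param input_csv Optional path of a lake-table CSV to load instead of
#'   simulating.
#' @param kinds Dataset kinds to model.
#' @param autocov_variants Logical vector: fit each kind without and/or with
#'   the spatial autocovariate.
#' @param n_pseudo Pseudoabsences per presence-only dataset (NULL = number of
#'   surveyed true absences).
#' @param autocov_radius Distance band for [add_autocovariate()].
#' @param n_folds,cv_iterations Nonindependent CV settings.
#' @param block_side,block_side_proximal Spatial block sides.
#' @param k_folds_blocked Spatial folds.
#' @param ntree Trees per forest.
#' @param importance_repeats Permutations per feature for importance.
#' @param seed Mandatory integer seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(simulation = simulation_config(seed = seed),
                              input_csv = NULL,
                              kinds = c("PA", "PO_random", "PO_distant",
                                        "PO_proximal", "ABUNDANCE"),
                              autocov_variants = c(FALSE, TRUE),
                              n_pseudo = NULL,
                              autocov_radius = "auto",
                              n_folds = 5, cv_iterations = 50,
                              block_side = 10, block_side_proximal = 5,
                              k_folds_blocked = 5,
                              ntree = 500,
                              importance_repeats = 10,
                              seed = 1) {
  if (missing(seed) && is.null(input_csv)) seed <- simulation$seed
  if (length(seed) != 1 || is.na(seed)) stop("seed is mandatory")
  if (!is.null(input_csv) && !file.exists(input_csv))
    stop("input_csv does not exist: ", input_csv)
  kinds <- match.arg(kinds, several.ok = TRUE)
  structure(list(simulation = simulation, input_csv = input_csv,
                 kinds = kinds, autocov_variants = autocov_variants,
                 n_pseudo = n_pseudo, autocov_radius = autocov_radius,
                 n_folds = n_folds, cv_iterations = cv_iterations,
                 block_side = block_side,
                 block_side_proximal = block_side_proximal,
                 k_folds_blocked = k_folds_blocked, ntree = ntree,
                 importance_repeats = importance_repeats,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

model_tag <- function(kind, autocov) paste0(kind, if (autocov) "_autocov")

## One model variant end to end: discrimination under the three schemes
## (occurrence kinds only), held-out importance + partial dependence, a
## full-data refit for suitability maps, functional accuracy and the wedge.
run_model_variant <- function(table, dataset, config, autocov) {
  kind <- dataset$kind
  occurrence <- kind != "ABUNDANCE"
  if (autocov)
    dataset <- suppressMessages(
      add_autocovariate(dataset, config$autocov_radius))
  bs <- if (kind == "PO_proximal") config$block_side_proximal
    else config$block_side
  seed_of <- function(off)
    as.integer((as.numeric(config$seed) * 97 + off) %% 2147483647)

  disc <- NULL
  if (occurrence) {
    schemes <- c(nonindependent = 11L, quasi_independent = 12L,
                 spatially_blocked = 13L)
    disc <- lapply(names(schemes), function(sch) evaluate_discrimination(
      dataset, sch, n_folds = config$n_folds, n_iter = config$cv_iterations,
      block_side = bs, k_folds_blocked = config$k_folds_blocked,
      ntree = config$ntree, seed = seed_of(schemes[[sch]])))
    names(disc) <- names(schemes)
  }

  split_fit <- fit_sdm(dataset, split = 0.7, ntree = config$ntree,
                       seed = seed_of(101L))
  importance <- permutation_importance(split_fit,
                                       n_repeats = config$importance_repeats)
  top3 <- importance$covariate[1:3]
  pdp <- do.call(rbind, lapply(top3, function(v)
    partial_dependence(split_fit, v)))

  full_fit <- fit_sdm(dataset, split = 1, ntree = config$ntree,
                      seed = seed_of(202L))
  func <- wedge <- NULL
  if (occurrence) {
    suit <- sdm_suitability(full_fit, table)
    fo <- table$freq_occ[match(names(suit), table$id)]
    func <- functional_accuracy(suit, fo)
    wedge <- wedge_quantiles(suit, fo)
  }
  list(kind = kind, autocov = autocov, tag = model_tag(kind, autocov),
       discrimination = disc, importance = importance, pdp = pdp,
       functional = func, wedge = wedge, full_fit = full_fit)
}

report_row <- function(v) {
  d <- v$discrimination
  g <- function(sch, m) if (is.null(d)) NA_real_ else d[[sch]][[m]]
  row <- data.frame(
    model = v$tag, kind = v$kind, autocov = v$autocov,
    auc_nonindependent = g("nonindependent", "auc"),
    tss_nonindependent = g("nonindependent", "tss"),
    kappa_nonindependent = g("nonindependent", "kappa"),
    auc_quasi_independent = g("quasi_independent", "auc"),
    tss_quasi_independent = g("quasi_independent", "tss"),
    kappa_quasi_independent = g("quasi_independent", "kappa"),
    auc_spatially_blocked = g("spatially_blocked", "auc"),
    tss_spatially_blocked = g("spatially_blocked", "tss"),
    kappa_spatially_blocked = g("spatially_blocked", "kappa"))
  for (m in c("auc", "tss", "kappa"))
    row[[paste0(m, "_combined")]] <-
      mean(c(row[[paste0(m, "_nonindependent")]],
             row[[paste0(m, "_quasi_independent")]],
             row[[paste0(m, "_spatially_blocked")]]))
  f <- v$functional
  row$r_all <- if (is.null(f)) NA_real_ else f$r_all
  row$r_nonzero <- if (is.null(f)) NA_real_ else f$r_nonzero
  row$rho_all <- if (is.null(f)) NA_real_ else f$rho_all
  row$rho_nonzero <- if (is.null(f)) NA_real_ else f$rho_nonzero
  row
}

#' Run the full modelling experiment
#'
#' Simulates (or loads) a lake table, builds the five response datasets,
#' fits every requested model variant (dataset kind x with/without spatial
#' autocovariate), evaluates occurrence models under the three discrimination
#' schemes and by functional accuracy plus the quantile wedge, computes
#' permutation importance and partial dependence for every model, and runs
#' Moran's I permutation diagnostics on the residuals of the presence-absence
#' and abundance models. With an output directory it also writes the lake
#' table, dataset CSVs, importance/PDP/wedge/evaluation CSVs, hull WKT and a
#' JSON run manifest.
#'
#' @param config An `experiment_config`.
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @return Invisibly, a list with `report` (the evaluation table, one row per
#'   occurrence model variant), `variants` (per-model artifacts), `morans`
#'   (residual diagnostics), `table` (the lake table) and `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  table <- stage("input", {
    if (is.null(config$input_csv)) generate_landscape(config$simulation)
    else read_lake_table(config$input_csv)
  })
  message(sprintf("lake table: %d lakes (%d surveyed)", nrow(table),
                  sum(table$surveyed)))

  set.seed(config$seed)
  datasets <- stage("datasets", {
    ds <- lapply(config$kinds, function(k)
      build_dataset(table, k, n_pseudo = config$n_pseudo))
    names(ds) <- config$kinds
    ds
  })
  for (k in names(datasets))
    message(sprintf("dataset %s: %d lakes", k, length(datasets[[k]]$ids)))

  variants <- stage("models", {
    out <- list()
    for (k in config$kinds)
      for (ac in config$autocov_variants)
        out[[model_tag(k, ac)]] <- run_model_variant(table, datasets[[k]],
                                                     config, ac)
    out
  })

  occ <- Filter(function(v) v$kind != "ABUNDANCE", variants)
  report <- do.call(rbind, lapply(occ, report_row))
  rownames(report) <- NULL

  morans <- stage("residual diagnostics", {
    out <- list()
    for (k in intersect(c("PA", "ABUNDANCE"), config$kinds)) {
      v <- variants[[model_tag(k, FALSE)]]
      if (is.null(v)) next
      ds <- v$full_fit$dataset
      res <- ds$label - v$full_fit$oob
      w <- build_weights(ds$coords, "auto")
      set.seed(config$seed + 7L)
      out[[k]] <- morans_i(w, res, n_perm = 999)
    }
    out
  })

  result <- list(report = report, variants = variants, morans = morans,
                 table = table, datasets = datasets, config = config)
  if (!is.null(out_dir)) stage("outputs", write_artifacts(result, out_dir))
  invisible(result)
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_lake_table(result$table, p("lake_table.csv"))
  for (k in names(result$datasets))
    write_response_dataset(result$datasets[[k]], p(paste0("dataset_", k, ".csv")))
  if ("PA" %in% names(result$datasets))
    writeLines(hull_to_wkt(presence_hull(result$table)), p("presence_hull.wkt"))
  for (v in result$variants) {
    utils::write.csv(v$importance, p(paste0("importance_", v$tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(v$pdp, p(paste0("pdp_", v$tag, ".csv")),
                     row.names = FALSE)
    if (!is.null(v$wedge)) {
      w <- v$wedge
      w$model <- v$tag
      w$wedge_strength <- attr(v$wedge, "wedge_strength")
      utils::write.csv(w, p(paste0("wedge_", v$tag, ".csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(result$report, p("evaluation.csv"), row.names = FALSE)
  if (length(result$morans) > 0) {
    md <- do.call(rbind, lapply(names(result$morans), function(k)
      data.frame(model = k, I = result$morans[[k]]$I,
                 p = result$morans[[k]]$p)))
    utils::write.csv(md, p("morans_residuals.csv"), row.names = FALSE)
  }
  manifest <- list(
    seed = result$config$seed,
    kinds = result$config$kinds,
    autocov_variants = result$config$autocov_variants,
    cv = list(n_folds = result$config$n_folds,
              iterations = result$config$cv_iterations,
              block_side = result$config$block_side,
              block_side_proximal = result$config$block_side_proximal,
              k_folds_blocked = result$config$k_folds_blocked),
    ntree = result$config$ntree,
    simulated = is.null(result$config$input_csv),
    package_version = as.character(utils::packageVersion("milfoilSDM")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Replicate the experiment across seeds
#'
#' Runs [run_experiment()] on `n_seeds` seeded landscapes and summarises the
#' headline contrast between discrimination and functional accuracy: per-seed
#' evaluation rows, per-model medians, and the signs of
#' `median AUC(PO_distant) - median AUC(PA)` (combined average) and
#' `median r_all(PA) - median r_all(PO_distant)`.
#'
#' @param config An `experiment_config`; its seed anchors the seed sequence
#'   `seed, seed + 1, ...`.
#' @param n_seeds Number of replicate landscapes (>= 2).
#' @return A `replicate_summary` list: `per_seed` (stacked report rows with a
#'   `seed` column), `medians`, and `signs`.
#' @export
replicate_study <- function(config, n_seeds = 20) {
  stopifnot(inherits(config, "experiment_config"))
  if (n_seeds < 2) stop("n_seeds must be >= 2")
  seeds <- config$seed + seq_len(n_seeds) - 1
  per_seed <- do.call(rbind, lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    cfg$simulation$seed <- as.integer(s)
    rep <- suppressMessages(run_experiment(cfg))$report
    rep$seed <- s
    rep
  }))
  metric_cols <- setdiff(names(per_seed),
                         c("model", "kind", "autocov", "seed"))
  medians <- do.call(rbind, lapply(split(per_seed, per_seed$model),
    function(d) {
      out <- d[1, c("model", "kind", "autocov")]
      for (m in metric_cols) out[[m]] <- stats::median(d[[m]], na.rm = TRUE)
      out
    }))
  rownames(medians) <- NULL
  signs <- list()
  if (all(c("PO_distant", "PA") %in% medians$model)) {
    auc_diff <- medians$auc_combined[medians$model == "PO_distant"] -
      medians$auc_combined[medians$model == "PA"]
    r_diff <- medians$r_all[medians$model == "PA"] -
      medians$r_all[medians$model == "PO_distant"]
    signs <- list(auc_po_distant_minus_pa = auc_diff,
                  r_all_pa_minus_po_distant = r_diff,
                  reversal = auc_diff > 0 && r_diff > 0)
  }
  structure(list(per_seed = per_seed, medians = medians, signs = signs,
                 seeds = seeds),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicated experiment over %d seeds\n", length(x$seeds)))
  print.data.frame(x$medians[, c("model", "auc_combined", "tss_combined",
                                 "kappa_combined", "r_all", "rho_all")],
                   row.names = FALSE, digits = 3)
  if (length(x$signs)) {
    cat(sprintf("median AUC (PO_distant - PA): %+.3f\n",
                x$signs$auc_po_distant_minus_pa))
    cat(sprintf("median r_all (PA - PO_distant): %+.3f\n",
                x$signs$r_all_pa_minus_po_distant))
    cat(sprintf("discrimination/functional reversal: %s\n",
                if (x$signs$reversal) "present" else "absent"))
  }
  invisible(x)
}
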