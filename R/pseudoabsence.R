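#' Convex hull of invaded lakes and partition of candidate lakes
#'
#' Computes the planar convex hull of the presence (invaded) lakes and splits
#' the candidate pool -- the unsurveyed lakes -- into those inside (or on) the
#' hull and those outside it. This partition underlies the distant and
#' proximal pseudoabsence selection strategies.
#'
#' @param table A `lake_table` with surveyed presences.
#' @return A `hull_partition`: list with `hull` (ordered vertex matrix,
#'   counter-clockwise), `inside_ids` and `outside_ids` (unsurveyed lake ids).
#' @export
presence_hull <- function(table) {
  pres <- table[table$surveyed & table$presence == 1, ]
  pts <- unique(cbind(pres$x, pres$y))
  if (nrow(pts) < 3)
    stop("degenerate hull: need at least 3 distinct presence locations")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3)
    stop("degenerate hull: presence locations are collinear")
  hull <- pts[rev(h), , drop = FALSE]   # chull is clockwise; reverse to CCW
  colnames(hull) <- c("x", "y")
  cand <- table[!table$surveyed, ]
  inside <- points_in_hull(cbind(cand$x, cand$y), hull)
  structure(list(hull = hull,
                 inside_ids = cand$id[inside],
                 outside_ids = cand$id[!inside]),
            class = "hull_partition")
}

#' @export
print.hull_partition <- function(x, ...) {
  cat(sprintf("Convex hull of presences: %d vertices; candidates %d inside, %d outside\n",
              nrow(x$hull), length(x$inside_ids), length(x$outside_ids)))
  invisible(x)
}

#' Test points against a convex polygon
#'
#' Half-plane test for a counter-clockwise convex polygon: a point is inside
#' iff it lies on the left of (or on) every directed edge. Boundary points
#' count as inside, the deterministic tie-break used by the proximal
#' pseudoabsence strategy.
#'
#' @param points Two-column coordinate matrix.
#' @param hull Ordered (counter-clockwise) vertex matrix of a convex polygon.
#' @return Logical vector, TRUE = inside or on the boundary.
#' @export
points_in_hull <- function(points, hull) {
  points <- matrix(as.numeric(points), ncol = 2)
  nv <- nrow(hull)
  eps <- 1e-9 * max(abs(hull), 1)
  inside <- rep(TRUE, nrow(points))
  for (k in seq_len(nv)) {
    a <- hull[k, ]; b <- hull[if (k == nv) 1 else k + 1, ]
    cross <- (b[1] - a[1]) * (points[, 2] - a[2]) -
      (b[2] - a[2]) * (points[, 1] - a[1])
    inside <- inside & (cross >= -eps)
  }
  inside
}

#' Export a hull as a WKT polygon
#'
#' @param partition A `hull_partition`.
#' @return A closed `POLYGON ((...))` WKT string.
#' @export
hull_to_wkt <- function(partition) {
  v <- rbind(partition$hull, partition$hull[1, , drop = FALSE])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6f %.6f", v[, 1], v[, 2]), collapse = ", "))
}

new_response_dataset <- function(kind, table, ids, label, role,
                                 autocov = FALSE) {
  idx <- match(ids, table$id)
  features <- table[idx, lake_covariate_names(table), drop = FALSE]
  rownames(features) <- NULL
  structure(list(kind = kind, ids = ids, label = label, role = role,
                 coords = cbind(x = table$x[idx], y = table$y[idx]),
                 features = features, has_autocov = autocov),
            class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(sprintf("Response dataset [%s]: %d lakes (%s)%s\n", x$kind,
              length(x$ids),
              paste(sprintf("%d %s", table(x$role), names(table(x$role))),
                    collapse = ", "),
              if (x$has_autocov) " + autocovariate" else ""))
  invisible(x)
}

#' Draw pseudoabsences and assemble a presence-only dataset
#'
#' Implements the three pseudoabsence selection strategies: `random` draws
#' uniformly without replacement from all unsurveyed lakes; `distant` from
#' unsurveyed lakes outside the convex hull of invaded lakes; `proximal` from
#' unsurveyed lakes inside that hull. Surveyed true absences are excluded
#' entirely -- pseudoabsences replace them rather than augment them. If the
#' strategy's candidate cell holds fewer than `n_pseudo` lakes the draw fails
#' explicitly; it is never topped up from the other cell.
#'
#' @param table A `lake_table`.
#' @param strategy One of `"random"`, `"distant"`, `"proximal"`.
#' @param n_pseudo Number of pseudoabsences; defaults to the number of
#'   surveyed true absences so class balance matches the presence-absence
#'   dataset.
#' @return A `response_dataset` with binary labels (presence 1,
#'   pseudoabsence 0).
#' @export
draw_pseudoabsences <- function(table,
                                strategy = c("random", "distant", "proximal"),
                                n_pseudo = NULL) {
  strategy <- match.arg(strategy)
  validate_lake_table(table)
  if (is.null(n_pseudo))
    n_pseudo <- sum(table$surveyed & table$presence == 0)
  pool <- switch(strategy,
    random = table$id[!table$surveyed],
    distant = presence_hull(table)$outside_ids,
    proximal = presence_hull(table)$inside_ids)
  if (length(pool) < n_pseudo)
    stop(sprintf("strategy '%s' has only %d candidate lakes for %d pseudoabsences",
                 strategy, length(pool), n_pseudo))
  drawn <- if (length(pool) == n_pseudo) pool else sample(pool, n_pseudo)
  pres <- table$id[table$surveyed & table$presence == 1]
  new_response_dataset(
    kind = paste0("PO_", strategy), table = table,
    ids = c(pres, drawn),
    label = c(rep(1, length(pres)), rep(0, n_pseudo)),
    role = c(rep("presence", length(pres)), rep("pseudoabsence", n_pseudo)))
}

#' Assemble one of the five model-ready response datasets
#'
#' `PA` is the presence-absence dataset over surveyed lakes only; `PO_random`,
#' `PO_distant`, `PO_proximal` call [draw_pseudoabsences()]; `ABUNDANCE` is
#' the surveyed presence + absence set labelled with frequency of occurrence.
#' Lakes with any missing covariate are dropped complete-case style, with the
#' dropped count reported via `message()`.
#'
#' @param table A `lake_table`.
#' @param kind Dataset kind.
#' @param n_pseudo Passed to [draw_pseudoabsences()] for PO kinds.
#' @return A `response_dataset`.
#' @export
build_dataset <- function(table,
                          kind = c("PA", "PO_random", "PO_distant",
                                   "PO_proximal", "ABUNDANCE"),
                          n_pseudo = NULL) {
  kind <- match.arg(kind)
  cov_names <- lake_covariate_names(table)
  complete <- stats::complete.cases(table[, cov_names, drop = FALSE])
  if (any(!complete)) {
    message(sprintf("dropped %d lake(s) with incomplete covariates",
                    sum(!complete)))
    table <- table[complete, , drop = FALSE]
    class(table) <- c("lake_table", "data.frame")
  }
  ds <- if (kind %in% c("PO_random", "PO_distant", "PO_proximal")) {
    draw_pseudoabsences(table, sub("^PO_", "", kind), n_pseudo)
  } else {
    validate_lake_table(table)
    sv <- table[table$surveyed, ]
    label <- if (kind == "ABUNDANCE") sv$freq_occ else sv$presence
    new_response_dataset(kind, table, sv$id, label,
                         ifelse(sv$presence == 1, "presence", "absence"))
  }
  if (length(ds$ids) == 0) stop("empty dataset")
  if (anyDuplicated(ds$ids)) stop("a lake appears twice in the dataset")
  ds
}

#' Round-trip a response dataset through CSV
#'
#' Columns `id,x,y,role,label,<covariates>[,autocov]`.
#'
#' @param dataset A `response_dataset`.
#' @param path File path.
#' @param kind Dataset kind (needed on read; not stored in the CSV).
#' @return The path (write) or a `response_dataset` (read).
#' @export
write_response_dataset <- function(dataset, path) {
  df <- data.frame(id = dataset$ids, x = dataset$coords[, 1],
                   y = dataset$coords[, 2], role = dataset$role,
                   label = dataset$label, dataset$features,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_dataset
#' @export
read_response_dataset <- function(path, kind) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feat <- df[, setdiff(names(df), c("id", "x", "y", "role", "label")),
             drop = FALSE]
  structure(list(kind = kind, ids = df$id, label = df$label, role = df$role,
                 coords = cbind(x = df$x, y = df$y), features = feat,
                 has_autocov = "autocov" %in% names(feat)),
            class = "response_dataset")
}

#' Append the spatial autocovariate to a dataset's features
#'
#' Builds distance-band inverse-distance weights over the dataset's own lakes
#' and adds the spatial lag of its response as an `autocov` feature column.
#' Deliberately computed once on the full dataset before any train/test
#' split, mirroring its use as an auxiliary predictor alongside the
#' environmental covariates; the implied leakage into held-out folds is
#' announced via `message()`.
#'
#' @param dataset A `response_dataset`.
#' @param radius Distance band passed to [build_weights()] (default "auto").
#' @return The dataset with `features$autocov` added and `has_autocov = TRUE`.
#' @export
add_autocovariate <- function(dataset, radius = "auto") {
  stopifnot(inherits(dataset, "response_dataset"))
  w <- build_weights(dataset$coords, radius)
  dataset$features$autocov <- autocovariate(w, dataset$label)
  dataset$has_autocov <- TRUE
  dataset$autocov_radius <- w$radius
  message(sprintf("autocovariate computed on all %d lakes before any split (radius %.2f)",
                  length(dataset$ids), w$radius))
  dataset
}
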