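#' Default lake-level covariate specification
#'
#' Summary statistics (mean, SD, min, max) of the 11 lake-level environmental
#' predictors used throughout the package, matching the Minnesota survey data
#' the pipeline was designed around: water colour (CDOM absorption at 440 nm),
#' chlorophyll-a, specific conductance, water-temperature growing degree days
#' (base 10 C), maximum lake depth, lake size, pH, total phosphorus, road
#' density and stream density within 500 m of the lake, and Secchi depth.
#' `range_km` is the spatial correlation range used by the landscape simulator
#' for each covariate, and `ns_gradient` the fraction of a covariate's spatial
#' variance carried by a deterministic north-south trend: growing degree days
#' get a long range and a strong latitudinal gradient, the dominant spatial
#' structure of thermal habitat across a 5-degree latitude span, while water
#' chemistry and connectivity vary at the scale of a few tens of km.
#'
#' @return A data.frame with columns `name`, `mean`, `sd`, `min`, `max`,
#'   `range_km`, `ns_gradient`, one row per covariate.
#' @export
default_covariate_spec <- function() {
  data.frame(
    name = c("cdom_a440", "chlorophyll_a", "conductance", "gdd_wtr_10c",
             "lake_depth", "lake_size", "ph", "phosphorus", "road_density",
             "secchi_depth", "stream_density"),
    mean = c(2.38, 31, 313, 1671, 10.2, 759, 8.03, 0.090, 40.6, 2.35, 4.18),
    sd   = c(2.27, 84, 215, 225, 9.58, 4984, 0.633, 0.116, 29.3, 1.48, 3.5),
    min  = c(0, 0.093, 8.53, 1078, 0.914, 8.82, 6.02, 0.004, 0, 0.167, 0),
    max  = c(15.1, 2231, 1750, 2465, 141, 128251, 9.71, 1.18, 211, 12.9, 21.2),
    range_km = c(25, 25, 30, 250, 40, 30, 30, 25, 40, 30, 25),
    ns_gradient = c(0, 0, 0, 0.98, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a simulated lake landscape
#'
#' Assembles and validates the full recipe for [generate_landscape()]: how many
#' surveyed presence/absence lakes and unsurveyed lakes to produce, the planar
#' extent, the per-covariate moments and spatial ranges, which covariates drive
#' true suitability and where their responses plateau, and the point-intercept
#' and abundance-wedge parameters. Defaults reproduce the structure of the
#' Minnesota watermilfoil dataset: 184 invaded and 284 uninvaded surveyed lakes
#' plus 801 unsurveyed lakes over a roughly 600 x 560 km region, suitability
#' driven by growing degree days (plateau ~1750 degree-days), lake depth
#' (plateau ~30 m) and road density (plateau ~75 m/ha), and a right-skewed
#' frequency of occurrence capped near 0.8.
#'
#' @param n_presence,n_absence,n_unsurveyed Lake counts (positive integers).
#' @param extent Numeric length-2, width and height of the rectangular study
#'   region in km.
#' @param covariate_spec Data.frame as returned by [default_covariate_spec()].
#' @param active_covariates Names of the covariates that generate true
#'   suitability; must appear in `covariate_spec$name`.
#' @param suitability_params List with `plateaus` (named numeric, one value
#'   per active covariate, inside that covariate's range), `onsets` (where
#'   each saturating ramp starts rising; defaults to the covariate minimum),
#'   `weights` (logit-scale effect sizes), `intercept`, and optionally
#'   `gate`, the name of an active covariate whose ramp multiplies the other
#'   active contributions. By default growing degree days are the gate: the
#'   steep thermal ramp (weight 20 up to the 1750 degree-day plateau)
#'   confines the species to a compact southern band -- the geography that
#'   makes distant and proximal pseudoabsence draws meaningfully different --
#'   while depth and road density modulate suitability within that band but
#'   cannot rescue thermally unsuitable lakes. Set `gate = NULL` for a plain
#'   additive logistic.
#' @param n_points_per_lake Point-intercept grid size used to sample frequency
#'   of occurrence within each lake.
#' @param abundance_shape Length-2 Beta shape parameters of the latent cover
#'   multiplier; the default Beta(1.3, 2.2) has mean < 0.5 and positive skew,
#'   producing the wedge-shaped abundance-suitability pattern.
#' @param max_cover Upper bound on true within-lake cover (frequency of
#'   occurrence scale); observed values then range over [0, `max_cover`] up to
#'   binomial sampling noise.
#' @param placement `"uniform"` for complete spatial randomness of lake
#'   locations, `"clustered"` for a Thomas-process layout.
#' @param cluster_scale Gaussian dispersion (km) of offspring around cluster
#'   parents when `placement = "clustered"`.
#' @param latent_spatial_sd Standard deviation (logit scale) of an additional
#'   smooth spatial field added to true suitability but absent from the
#'   covariates. Zero (the default) means occurrence is fully explained by the
#'   covariates; positive values create residual spatial autocorrelation that
#'   an autocovariate term can absorb.
#' @param latent_spatial_range Correlation range (km) of that latent field.
#' @param survey_bias Nonnegative coefficient linking survey probability to
#'   suitability; 0 (default) surveys lakes at random.
#' @param resample_budget Maximum number of Bernoulli redraws allowed when
#'   matching the configured presence/absence counts.
#' @param seed Integer seed; fully determines the generated landscape.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_presence = 184,
                              n_absence = 284,
                              n_unsurveyed = 801,
                              extent = c(600, 560),
                              covariate_spec = default_covariate_spec(),
                              active_covariates = c("gdd_wtr_10c", "lake_depth",
                                                    "road_density"),
                              suitability_params = list(
                                plateaus = c(gdd_wtr_10c = 1750,
                                             lake_depth = 30,
                                             road_density = 75),
                                onsets = c(gdd_wtr_10c = 1078),
                                weights = c(gdd_wtr_10c = 20,
                                            lake_depth = 9,
                                            road_density = 8),
                                intercept = -26.5,
                                gate = "gdd_wtr_10c"
                              ),
                              n_points_per_lake = 100,
                              abundance_shape = c(1.3, 2.2),
                              max_cover = 0.8,
                              placement = c("uniform", "clustered"),
                              cluster_scale = 10,
                              latent_spatial_sd = 0,
                              latent_spatial_range = 40,
                              survey_bias = 0,
                              resample_budget = 100,
                              seed = 1) {
  placement <- match.arg(placement)
  counts <- c(n_presence = n_presence, n_absence = n_absence,
              n_unsurveyed = n_unsurveyed)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("lake counts must be positive integers")
  if (length(extent) != 2 || any(extent <= 0))
    stop("extent must be two positive lengths (km)")
  req <- c("name", "mean", "sd", "min", "max", "range_km")
  if (!all(req %in% names(covariate_spec)))
    stop("covariate_spec must have columns ", paste(req, collapse = ", "))
  if (is.null(covariate_spec$ns_gradient)) covariate_spec$ns_gradient <- 0
  if (any(covariate_spec$ns_gradient < 0 | covariate_spec$ns_gradient > 1))
    stop("ns_gradient must lie in [0, 1]")
  with(covariate_spec, {
    if (any(min > mean | mean > max))
      stop("covariate_spec requires min <= mean <= max for every covariate")
    if (any(sd <= 0) || any(range_km <= 0))
      stop("covariate sd and range_km must be positive")
  })
  if (!all(active_covariates %in% covariate_spec$name))
    stop("active_covariates must name rows of covariate_spec")
  pl <- suitability_params$plateaus
  if (!all(active_covariates %in% names(pl)))
    stop("suitability_params$plateaus must cover every active covariate")
  for (v in active_covariates) {
    row <- covariate_spec[covariate_spec$name == v, ]
    if (pl[[v]] <= row$min || pl[[v]] > row$max)
      stop("plateau for ", v, " must lie inside its covariate range")
    on <- if (is.null(suitability_params$onsets)) NA_real_
      else unname(suitability_params$onsets[v])
    if (length(on) == 1 && !is.na(on) && (on < row$min || on >= pl[[v]]))
      stop("onset for ", v, " must lie in [covariate min, plateau)")
  }
  if (!all(active_covariates %in% names(suitability_params$weights)))
    stop("suitability_params$weights must cover every active covariate")
  if (n_points_per_lake < 1) stop("n_points_per_lake must be >= 1")
  if (length(abundance_shape) != 2 || any(abundance_shape <= 0))
    stop("abundance_shape must be two positive Beta parameters")
  if (max_cover <= 0 || max_cover > 1) stop("max_cover must be in (0, 1]")
  if (length(seed) != 1 || is.na(seed)) stop("seed is mandatory")
  structure(list(
    n_presence = as.integer(n_presence), n_absence = as.integer(n_absence),
    n_unsurveyed = as.integer(n_unsurveyed), extent = as.numeric(extent),
    covariate_spec = covariate_spec, active_covariates = active_covariates,
    suitability_params = suitability_params,
    n_points_per_lake = as.integer(n_points_per_lake),
    abundance_shape = as.numeric(abundance_shape), max_cover = max_cover,
    placement = placement, cluster_scale = cluster_scale,
    latent_spatial_sd = latent_spatial_sd,
    latent_spatial_range = latent_spatial_range,
    survey_bias = survey_bias, resample_budget = as.integer(resample_budget),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulated landscape recipe\n")
  cat(sprintf("  lakes: %d presence + %d absence surveyed, %d unsurveyed\n",
              x$n_presence, x$n_absence, x$n_unsurveyed))
  cat(sprintf("  extent: %g x %g km (%s placement)\n", x$extent[1], x$extent[2],
              x$placement))
  cat(sprintf("  covariates: %d (%s active)\n", nrow(x$covariate_spec),
              paste(x$active_covariates, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

## Smooth Gaussian-kernel mixing of white noise at m random knots, evaluated
## at irregular lake locations; the workhorse behind every spatially
## autocorrelated surface in the simulator.
kernel_field <- function(coords, extent, range_km, n_knots = 150) {
  knots <- cbind(stats::runif(n_knots, 0, extent[1]),
                 stats::runif(n_knots, 0, extent[2]))
  z <- stats::rnorm(n_knots)
  d2 <- outer(coords[, 1], knots[, 1], "-")^2 +
    outer(coords[, 2], knots[, 2], "-")^2
  f <- exp(-d2 / (2 * range_km^2)) %*% z
  as.numeric(scale(f))
}

#' Simulate a Thomas cluster point pattern with a fixed number of points
#'
#' Parents are uniform over the window; each of `n` points is attached to a
#' random parent and displaced by an isotropic Gaussian of standard deviation
#' `cluster_scale`, wrapped on the torus so the intensity stays homogeneous.
#'
#' @param n Number of points.
#' @param extent Window as c(width, height).
#' @param cluster_scale Gaussian cluster dispersion (same units as extent).
#' @param points_per_cluster Expected offspring per parent (controls the
#'   parent count `ceiling(n / points_per_cluster)`).
#' @return An `n` x 2 coordinate matrix.
#' @export
simulate_thomas <- function(n, extent, cluster_scale, points_per_cluster = 8) {
  n_parents <- max(1L, ceiling(n / points_per_cluster))
  parents <- cbind(stats::runif(n_parents, 0, extent[1]),
                   stats::runif(n_parents, 0, extent[2]))
  idx <- sample.int(n_parents, n, replace = TRUE)
  pts <- parents[idx, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, sd = cluster_scale), ncol = 2)
  pts[, 1] <- pts[, 1] %% extent[1]
  pts[, 2] <- pts[, 2] %% extent[2]
  pts
}

place_lakes <- function(n, config) {
  if (config$placement == "uniform") {
    cbind(stats::runif(n, 0, config$extent[1]),
          stats::runif(n, 0, config$extent[2]))
  } else {
    simulate_thomas(n, config$extent, config$cluster_scale)
  }
}

## Saturating-ramp transform: linear from the covariate's minimum up to the
## plateau, flat beyond it, scaled to [0, 1].
ramp <- function(x, lo, plateau) {
  pmin(pmax((x - lo) / (plateau - lo), 0), 1)
}

true_suitability <- function(X, coords, config) {
  sp <- config$suitability_params
  eta <- rep(sp$intercept, nrow(X))
  onset_of <- function(v, row_min) {
    lo <- if (is.null(sp$onsets)) NA_real_ else unname(sp$onsets[v])
    if (length(lo) != 1 || is.na(lo)) row_min else lo
  }
  gate_var <- sp$gate
  gate <- 1
  if (!is.null(gate_var) && gate_var %in% config$active_covariates) {
    row <- config$covariate_spec[config$covariate_spec$name == gate_var, ]
    gate <- ramp(X[, gate_var], onset_of(gate_var, row$min),
                 sp$plateaus[[gate_var]])
    eta <- eta + sp$weights[[gate_var]] * gate
  } else {
    gate_var <- NULL
  }
  for (v in setdiff(config$active_covariates, gate_var)) {
    row <- config$covariate_spec[config$covariate_spec$name == v, ]
    eta <- eta + gate * sp$weights[[v]] *
      ramp(X[, v], onset_of(v, row$min), sp$plateaus[[v]])
  }
  if (config$latent_spatial_sd > 0) {
    eta <- eta + config$latent_spatial_sd *
      kernel_field(coords, config$extent, config$latent_spatial_range)
  }
  stats::plogis(eta)
}

#' Simulate a point-intercept survey of within-lake cover
#'
#' Emulates the rake-based point-intercept protocol: `n_points` sample points
#' on a within-lake grid, each detecting the plant independently with
#' probability `true_cover`; the returned frequency of occurrence is the
#' detected fraction.
#'
#' @param true_cover True within-lake cover in [0, 1] (vectorised).
#' @param n_points Number of sample points per lake (>= 1).
#' @return Frequency of occurrence in [0, 1], same length as `true_cover`.
#' @export
simulate_point_intercept <- function(true_cover, n_points) {
  if (any(true_cover < 0 | true_cover > 1, na.rm = TRUE))
    stop("true_cover must lie in [0, 1]")
  if (n_points < 1) stop("n_points must be >= 1")
  stats::rbinom(length(true_cover), n_points, true_cover) / n_points
}

#' Attach frequency-of-occurrence abundance to a simulated landscape
#'
#' For each surveyed presence the true cover is `max_cover * s * u`, where `s`
#' is the lake's true suitability and `u` a right-skewed Beta multiplier (so
#' suitability bounds cover from above but does not determine it -- the wedge),
#' and the observed frequency of occurrence is a point-intercept binomial
#' sample of that cover. Surveyed absences get frequency 0; unsurveyed lakes
#' stay NA. A presence whose binomial sample comes back 0 is resampled once,
#' then floored at one detection, so presence always implies positive
#' frequency.
#'
#' @param table A `lake_table` carrying a `s_true` column.
#' @param config The `simulation_config` used to generate the table.
#' @return The table with its `freq_occ` column filled in.
#' @export
assign_abundance <- function(table, config) {
  stopifnot(is.data.frame(table), "s_true" %in% names(table))
  pres <- which(table$surveyed & table$presence == 1)
  u <- stats::rbeta(length(pres), config$abundance_shape[1],
                    config$abundance_shape[2])
  cover <- config$max_cover * table$s_true[pres] * u
  fo <- simulate_point_intercept(cover, config$n_points_per_lake)
  zero <- fo == 0
  if (any(zero))
    fo[zero] <- simulate_point_intercept(cover[zero], config$n_points_per_lake)
  fo[fo == 0] <- 1 / config$n_points_per_lake
  table$freq_occ[pres] <- fo
  table$freq_occ[table$surveyed & table$presence == 0] <- 0
  table
}

#' Generate a seeded virtual lake landscape
#'
#' Produces a complete lake table emulating the structure of the Minnesota
#' watermilfoil survey: lake locations over a rectangular extent, spatially
#' autocorrelated environmental covariates rescaled to the configured moments
#' and clipped to their observed ranges, a true suitability surface built from
#' saturating-ramp transforms of the active covariates through a logistic
#' link, Bernoulli occurrence redrawn until the configured presence/absence
#' counts are available, random assignment of survey status, and
#' point-intercept frequency of occurrence with a wedge-shaped relation to
#' suitability (via [assign_abundance()]).
#'
#' The returned table keeps the simulation truth (`s_true`) as an extra
#' column; [write_lake_table()] omits it so the on-disk format matches what a
#' real survey would provide.
#'
#' @param config A `simulation_config`.
#' @return A `lake_table` data.frame with columns `id`, `x`, `y`, `surveyed`,
#'   `presence`, `freq_occ`, the 11 covariates, and `s_true`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_presence + config$n_absence + config$n_unsurveyed
  coords <- place_lakes(n, config)
  spec <- config$covariate_spec
  X <- matrix(NA_real_, n, nrow(spec), dimnames = list(NULL, spec$name))
  trend <- as.numeric(scale(-coords[, 2]))  # warmer / denser to the south
  for (i in seq_len(nrow(spec))) {
    f <- kernel_field(coords, config$extent, spec$range_km[i])
    a <- spec$ns_gradient[i]
    f <- sqrt(a) * trend + sqrt(1 - a) * f
    X[, i] <- pmin(pmax(spec$mean[i] + spec$sd[i] * f, spec$min[i]),
                   spec$max[i])
  }
  s <- true_suitability(X, coords, config)

  y <- NULL
  for (attempt in seq_len(config$resample_budget)) {
    cand <- stats::rbinom(n, 1, s)
    if (sum(cand) >= config$n_presence &&
        sum(1 - cand) >= config$n_absence) { y <- cand; break }
  }
  if (is.null(y))
    stop(sprintf(paste0("could not realise %d presences and %d absences ",
                        "within the resampling budget of %d draws; adjust ",
                        "suitability_params or counts"),
                 config$n_presence, config$n_absence, config$resample_budget))

  w <- if (config$survey_bias > 0) exp(config$survey_bias * s) else NULL
  pres_idx <- sample(which(y == 1), config$n_presence,
                     prob = if (is.null(w)) NULL else w[y == 1])
  abs_idx <- sample(which(y == 0), config$n_absence,
                    prob = if (is.null(w)) NULL else w[y == 0])
  surveyed <- logical(n)
  surveyed[c(pres_idx, abs_idx)] <- TRUE

  table <- data.frame(
    id = sprintf("lake_%04d", seq_len(n)),
    x = coords[, 1], y = coords[, 2],
    surveyed = surveyed,
    presence = ifelse(surveyed, ifelse(seq_len(n) %in% pres_idx, 1L, 0L),
                      NA_integer_),
    freq_occ = NA_real_,
    stringsAsFactors = FALSE
  )
  table <- cbind(table, as.data.frame(X))
  table$s_true <- s
  table <- assign_abundance(table, config)
  class(table) <- c("lake_table", "data.frame")
  table
}

lake_covariate_names <- function(table) {
  setdiff(names(table), c("id", "x", "y", "surveyed", "presence", "freq_occ",
                          "s_true"))
}

validate_lake_table <- function(table) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(table$id)) stop("lake ids must be unique")
  sv <- table[table$surveyed, ]
  if (any(is.na(sv$presence)) || any(is.na(sv$freq_occ)))
    stop("surveyed lakes must have presence and freq_occ defined")
  if (any(sv$freq_occ[sv$presence == 0] != 0))
    stop("freq_occ must be 0 for surveyed absences")
  if (any(sv$freq_occ[sv$presence == 1] <= 0))
    stop("freq_occ must be positive for presences")
  cv <- table[, lake_covariate_names(table), drop = FALSE]
  if (!all(vapply(cv, function(z) all(is.finite(z) | is.na(z)), logical(1))))
    stop("covariates must be finite")
  invisible(table)
}

#' Write / read a lake table as plain CSV
#'
#' Fixed column order `id,x,y,surveyed,presence,freq_occ,<covariates>`;
#' undefined responses on unsurveyed lakes are written as empty fields. The
#' simulation-truth column `s_true`, if present, is dropped on write.
#'
#' @param table A `lake_table`.
#' @param path File path.
#' @return `write_lake_table` returns `path` invisibly; `read_lake_table`
#'   returns a validated `lake_table`.
#' @export
write_lake_table <- function(table, path) {
  cols <- c("id", "x", "y", "surveyed", "presence", "freq_occ",
            lake_covariate_names(table))
  utils::write.csv(table[, cols], path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_lake_table
#' @export
read_lake_table <- function(path) {
  table <- utils::read.csv(path, stringsAsFactors = FALSE)
  table$surveyed <- as.logical(table$surveyed)
  class(table) <- c("lake_table", "data.frame")
  validate_lake_table(table)
  table
}
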