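#' Configuration for the synthetic survey generator
#'
#' Describes a synthetic world emulating a DHS-style cluster survey of child
#' anthropometry together with the gridded environmental covariates the
#' model consumes: spatially clustered survey locations on a projected km
#' plane, temporally constant covariate rasters, monthly covariate series
#' with sinusoidal seasonality and spatially correlated anomalies, an
#' under-5 population raster, and z-score outcomes drawn from the exact
#' linear geostatistical model (intercept + standardized covariate effects
#' + exponential-correlation Gaussian process + Gaussian nugget).
#'
#' Defaults follow the survey this generator stands in for: 696 clusters on
#' a roughly 500 x 500 km country, 5-15 children per cluster, and HAZ-like
#' truth (alpha = -1.23, sigma2 = 0.15, phi = 18.28 km, omega2 = 2.02).
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in km; positive area.
#' @param n_clusters number of survey clusters (>= 2).
#' @param ind_range integer range `c(lo, hi)` of children per cluster.
#' @param true_params a [geo_params()]; `beta` names must reference
#'   covariates as `"<name>"` (constant) or `"<name>_lag<d>"` (monthly).
#' @param covariates data.frame with columns `name`, `kind` (`"constant"`
#'   or `"monthly"`), `range_km` (spatial correlation range of the field),
#'   `sd` (marginal SD), `seasonal_amp` (amplitude of the 12-month
#'   sinusoidal seasonal mean; ignored for constant covariates).
#' @param n_months length of the monthly series (>= 13 so that any lag
#'   0-12 exists for some birth month; default 36).
#' @param cellsize raster cell size in km for generated fields.
#' @param seed integer seed; every draw the generator makes derives from it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(extent = c(0, 500, 0, 500),
                       n_clusters = 696,
                       ind_range = c(5, 15),
                       true_params = geo_params(
                         alpha = -1.23,
                         beta = c(temperature = 0.10, spei_lag3 = 0.06),
                         sigma2 = 0.15, phi = 18.28, omega2 = 2.02),
                       covariates = default_covariates(),
                       n_months = 36,
                       cellsize = 10,
                       seed = 1L) {
  stopifnot(length(extent) == 4, all(is.finite(extent)))
  if ((extent[2] - extent[1]) <= 0 || (extent[4] - extent[3]) <= 0)
    stop("domain extent must have positive area", call. = FALSE)
  if (n_clusters < 2) stop("n_clusters must be >= 2", call. = FALSE)
  if (n_months < 13) stop("n_months must be >= 13", call. = FALSE)
  stopifnot(inherits(true_params, "geo_params"),
            length(ind_range) == 2, ind_range[1] >= 1,
            ind_range[2] >= ind_range[1])
  req <- c("name", "kind", "range_km", "sd")
  if (!all(req %in% names(covariates)))
    stop("'covariates' needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (is.null(covariates$seasonal_amp)) covariates$seasonal_amp <- 0
  if (!all(covariates$kind %in% c("constant", "monthly")))
    stop("covariate kind must be 'constant' or 'monthly'", call. = FALSE)
  if (any(covariates$sd < 0) || any(covariates$range_km <= 0))
    stop("covariate sd must be >= 0 and range_km > 0", call. = FALSE)
  structure(list(extent = extent, n_clusters = as.integer(n_clusters),
                 ind_range = as.integer(ind_range),
                 true_params = true_params, covariates = covariates,
                 n_months = as.integer(n_months), cellsize = cellsize,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default synthetic covariate inventory
#'
#' One temporally constant field (temperature-like) and three monthly
#' series: rainfall-like (strong 12-month seasonality), SPEI-like (a
#' standardized anomaly index, hence no seasonal cycle and unit marginal
#' SD), and EVI-like (moderate seasonality).
#'
#' @return data.frame accepted by [sim_config()].
#' @export
default_covariates <- function() {
  data.frame(
    name = c("temperature", "rainfall", "spei", "evi"),
    kind = c("constant", "monthly", "monthly", "monthly"),
    range_km = c(150, 100, 80, 60),
    sd = c(1, 1, 1, 0.8),
    seasonal_amp = c(0, 1, 0, 0.5))
}

#' Simulate cluster locations
#'
#' Uniform draws over the rectangular domain (stands in for the survey's
#' population-proportional sampling, which needs a census frame).
#'
#' @param config a [sim_config()].
#' @return data.frame `cluster_id`, `x_km`, `y_km`.
#' @export
sim_cluster_locations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_clusters
  ex <- config$extent
  repeat {
    x <- stats::runif(n, ex[1], ex[2])
    y <- stats::runif(n, ex[3], ex[4])
    if (!anyDuplicated(cbind(x, y))) break
  }
  data.frame(cluster_id = seq_len(n), x_km = x, y_km = y)
}

seasonal_mean <- function(month, amp, phase = 0) {
  amp * sin(2 * pi * (month + phase) / 12)
}

# one spatially correlated field drawn on a raster geometry
sim_field_raster <- function(geom, range_km, sd, mean = 0, chol_cache = NULL) {
  cc <- raster_cell_centers(geom)
  R <- chol_cache %||% gp_chol(cbind(cc$x, cc$y), range_km)
  z <- as.vector(crossprod(R, stats::rnorm(nrow(cc)))) * sd + mean
  geo_raster(matrix(z, nrow(geom$values), ncol(geom$values), byrow = TRUE),
             xll = geom$xll, yll = geom$yll, cellsize = geom$cellsize)
}

blank_geometry <- function(config) {
  ex <- config$extent
  nc <- max(2L, ceiling((ex[2] - ex[1]) / config$cellsize))
  nr <- max(2L, ceiling((ex[4] - ex[3]) / config$cellsize))
  geo_raster(matrix(0, nr, nc), xll = ex[1], yll = ex[3],
             cellsize = config$cellsize)
}

#' Simulate the covariate raster stack
#'
#' Constant covariates are single spatially correlated Gaussian fields;
#' monthly covariates are series of `n_months` rasters whose mean follows a
#' 12-month sinusoid and whose anomalies are spatially correlated
#' (exponential correlation at the configured range) and independent
#' between months.
#'
#' @param config a [sim_config()].
#' @return A `covariate_stack`: list with named `constant` rasters, named
#'   `monthly` lists of rasters (month 1 .. `n_months`), and the shared
#'   `geometry`.
#' @export
sim_covariate_fields <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$covariates) == 0)
    stop("covariate specification is empty", call. = FALSE)
  set.seed(config$seed + 1L)
  geom <- blank_geometry(config)
  cc <- raster_cell_centers(geom)
  constant <- list(); monthly <- list()
  for (i in seq_len(nrow(config$covariates))) {
    cv <- config$covariates[i, ]
    R <- gp_chol(cbind(cc$x, cc$y), cv$range_km)
    if (cv$kind == "constant") {
      constant[[cv$name]] <- sim_field_raster(geom, cv$range_km, cv$sd,
                                              chol_cache = R)
    } else {
      monthly[[cv$name]] <- lapply(seq_len(config$n_months), function(t)
        sim_field_raster(geom, cv$range_km, cv$sd,
                         mean = seasonal_mean(t, cv$seasonal_amp),
                         chol_cache = R))
    }
  }
  structure(list(constant = constant, monthly = monthly, geometry = geom),
            class = "covariate_stack")
}

#' Simulate monthly covariate values directly at point locations
#'
#' Same generative law as the monthly rasters (sinusoidal seasonal mean,
#' spatially correlated anomalies independent between months) but evaluated
#' at arbitrary points, which is all the model itself needs and is far
#' cheaper than rasterizing.
#'
#' @param coords 2-column matrix/data.frame of locations, km.
#' @param n_months series length.
#' @param range_km,sd,seasonal_amp field parameters as in [sim_config()].
#' @return matrix `nrow(coords)` x `n_months` (columns = months 1..).
#' @export
sim_monthly_at_points <- function(coords, n_months, range_km = 80, sd = 1,
                                  seasonal_amp = 0) {
  coords <- as.matrix(coords)
  R <- gp_chol(coords, range_km)
  out <- matrix(NA_real_, nrow(coords), n_months)
  for (t in seq_len(n_months)) {
    out[, t] <- as.vector(crossprod(R, stats::rnorm(nrow(coords)))) * sd +
      seasonal_mean(t, seasonal_amp)
  }
  colnames(out) <- seq_len(n_months)
  out
}

#' Simulate z-scores from the linear geostatistical model
#'
#' Draws one latent spatial effect per cluster from the multivariate normal
#' with covariance `sigma2 * exp(-u/phi)`, shares it across the cluster's
#' individuals, and adds iid `N(0, omega2)` individual effects, so the
#' returned outcomes are exactly `alpha + X beta + S[cluster] + U`.
#'
#' @param locations data.frame with `cluster_id`, `x_km`, `y_km` (one row
#'   per cluster).
#' @param cluster index of each individual's cluster (into `locations`).
#' @param X design matrix, one row per individual, columns matching
#'   `names(params$beta)` (use a 0-column matrix for an intercept-only
#'   model).
#' @param params a [geo_params()].
#' @param seed optional seed set before drawing.
#' @return data.frame `cluster_id`, `x_km`, `y_km`, `z`, plus the columns
#'   of `X`; attribute `"S"` carries the latent cluster effects.
#' @export
simulate_zscores <- function(locations, cluster, X, params, seed = NULL) {
  stopifnot(inherits(params, "geo_params"))
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- length(cluster)
  if (nrow(X) != n)
    stop("design matrix rows must align with individuals", call. = FALSE)
  if (ncol(X) != length(params$beta))
    stop("design columns must match length(params$beta)", call. = FALSE)
  m <- nrow(locations)
  if (any(cluster < 1 | cluster > m))
    stop("every individual must map to a cluster", call. = FALSE)
  if (params$sigma2 > 0) {
    C <- params$sigma2 *
      exp(-pair_dist(locations[, c("x_km", "y_km")]) / params$phi)
    S <- as.vector(rmvn(1, rep(0, m), C))
  } else S <- rep(0, m)
  mu <- params$alpha + if (ncol(X)) as.vector(X %*% params$beta) else 0
  U <- if (params$omega2 > 0) stats::rnorm(n, 0, sqrt(params$omega2)) else 0
  z <- mu + S[cluster] + U
  out <- data.frame(cluster_id = locations$cluster_id[cluster],
                    x_km = locations$x_km[cluster],
                    y_km = locations$y_km[cluster],
                    z = z)
  if (ncol(X)) out <- cbind(out, as.data.frame(X))
  attr(out, "S") <- S
  out
}

#' Simulate an under-5 population raster
#'
#' @param config a [sim_config()].
#' @param total total population to distribute (default 7.2 million,
#'   a national-scale under-5 population).
#' @param mode `"uniform"` (all cells equal) or `"clustered"` (log-Gaussian
#'   field weights).
#' @return [geo_raster()] of nonnegative integer counts summing to `total`
#'   up to rounding (largest-remainder correction makes the sum exact).
#' @export
sim_population_raster <- function(config, total = 7.2e6,
                                  mode = c("clustered", "uniform")) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  set.seed(config$seed + 2L)
  geom <- blank_geometry(config)
  ncell <- length(geom$values)
  w <- if (mode == "uniform") rep(1, ncell) else {
    f <- sim_field_raster(geom, range_km = 60, sd = 1)
    exp(raster_values(f))
  }
  target <- total * w / sum(w)
  counts <- floor(target)
  # largest-remainder so the raster total matches exactly
  rem <- round(total - sum(counts))
  if (rem > 0) {
    top <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  out <- geom
  out$values <- matrix(counts, nrow(geom$values), ncol(geom$values),
                       byrow = TRUE)
  out
}

#' Simulate a complete synthetic survey
#'
#' End-to-end generator: cluster locations, covariates (at cluster
#' locations; full rasters optionally), birth months, and z-scores from the
#' exact model. Monthly covariate effects in `true_params$beta` named
#' `"<name>_lag<d>"` act through the covariate value at the individual's
#' location `d` months before birth. Covariate columns are standardized
#' (mean 0, SD 1 over the sample) before the effects apply, matching a
#' per-1-SD coefficient scale.
#'
#' @param config a [sim_config()].
#' @param rasters if `TRUE`, also generate the full covariate raster stack
#'   (needed only for grid-prediction workflows; slower).
#' @return list of class `"geo_survey"`: `data` (one row per child:
#'   `cluster_id`, `x_km`, `y_km`, `birth_month`, standardized covariate
#'   columns, outcome `z`), `locations`, `monthly` (named list of
#'   cluster x month matrices), `stack` (if `rasters`), `truth`, `config`.
#' @export
simulate_survey <- function(config = sim_config(), rasters = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  loc <- sim_cluster_locations(config)
  stack <- if (rasters) sim_covariate_fields(config) else NULL

  set.seed(config$seed + 3L)
  sizes <- seq(config$ind_range[1], config$ind_range[2])
  n_i <- sizes[sample.int(length(sizes), config$n_clusters,
                          replace = TRUE)]
  cluster <- rep(seq_len(config$n_clusters), times = n_i)
  n <- length(cluster)
  # births restricted so every lag 0..12 exists in the series
  birth_month <- sample(13:config$n_months, n, replace = TRUE)

  # covariates at cluster locations
  set.seed(config$seed + 4L)
  const_vals <- list(); monthly <- list()
  for (i in seq_len(nrow(config$covariates))) {
    cv <- config$covariates[i, ]
    if (!is.null(stack)) {
      if (cv$kind == "constant") {
        const_vals[[cv$name]] <- extract_at_points(
          stack$constant[[cv$name]], loc$x_km, loc$y_km)
      } else {
        monthly[[cv$name]] <- vapply(stack$monthly[[cv$name]],
          function(r) as.numeric(extract_at_points(r, loc$x_km, loc$y_km)),
          numeric(config$n_clusters))
        colnames(monthly[[cv$name]]) <- seq_len(config$n_months)
      }
    } else {
      if (cv$kind == "constant") {
        R <- gp_chol(cbind(loc$x_km, loc$y_km), cv$range_km)
        const_vals[[cv$name]] <-
          as.vector(crossprod(R, stats::rnorm(config$n_clusters))) * cv$sd
      } else {
        monthly[[cv$name]] <- sim_monthly_at_points(
          cbind(loc$x_km, loc$y_km), config$n_months,
          range_km = cv$range_km, sd = cv$sd,
          seasonal_amp = cv$seasonal_amp)
      }
    }
  }

  # build the true-model design from beta's names
  bn <- names(config$true_params$beta)
  X <- matrix(NA_real_, n, length(bn), dimnames = list(NULL, bn))
  for (nm in bn) {
    lag <- lag_from_name(nm)
    if (is.na(lag)) {
      if (is.null(const_vals[[nm]]))
        stop("beta names a covariate not in the config: ", nm, call. = FALSE)
      X[, nm] <- const_vals[[nm]][cluster]
    } else {
      base <- sub("_lag[0-9]+$", "", nm)
      if (is.null(monthly[[base]]))
        stop("beta names a monthly covariate not in the config: ", base,
             call. = FALSE)
      X[, nm] <- build_lagged_column(monthly[[base]], cluster,
                                     birth_month, lag)
    }
  }
  X <- scale(X)[, , drop = FALSE]

  dat <- simulate_zscores(loc, cluster, X, config$true_params,
                          seed = config$seed + 5L)
  dat$birth_month <- birth_month
  # carry non-effect constant covariates too (standardized), for model search
  for (nm in names(const_vals)) {
    if (!nm %in% bn) dat[[nm]] <- as.vector(scale(const_vals[[nm]][cluster]))
  }
  structure(list(data = dat, locations = loc, monthly = monthly,
                 stack = stack, truth = config$true_params,
                 config = config),
            class = "geo_survey")
}

lag_from_name <- function(nm) {
  m <- regmatches(nm, regexec("_lag([0-9]+)$", nm))[[1]]
  if (length(m) == 2) as.integer(m[2]) else NA_integer_
}
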