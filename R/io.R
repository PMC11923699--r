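#' Read / write a cluster survey table
#'
#' CSV carrier for the per-individual survey records: comma-separated,
#' UTF-8, `.` decimal, header required. Required columns: `cluster_id`,
#' `x_km`, `y_km`, at least one z-score column (by default any of `z`,
#' `haz`, `waz`, `whz`), and `birth_month`.
#'
#' @param path CSV file.
#' @param zscore_cols acceptable outcome column names (at least one must
#'   be present).
#' @return validated data.frame; attributes `n_clusters`.
#' @export
read_cluster_table <- function(path,
                               zscore_cols = c("z", "haz", "waz", "whz")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(dat) == 0) stop("empty cluster table: ", path, call. = FALSE)
  req <- c("cluster_id", "x_km", "y_km", "birth_month")
  miss <- setdiff(req, names(dat))
  if (length(miss))
    stop("cluster table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!any(zscore_cols %in% names(dat)))
    stop("cluster table needs a z-score column (one of ",
         paste(zscore_cols, collapse = ", "), ")", call. = FALSE)
  for (cc in c("x_km", "y_km"))
    if (!is.numeric(dat[[cc]]))
      stop("column '", cc, "' is not numeric", call. = FALSE)
  if ("individual_id" %in% names(dat) &&
      anyDuplicated(dat[, c("cluster_id", "individual_id")]))
    stop("duplicate (cluster_id, individual_id) rows", call. = FALSE)
  attr(dat, "n_clusters") <- length(unique(dat$cluster_id))
  message(nrow(dat), " individuals in ", attr(dat, "n_clusters"),
          " clusters read from ", path)
  dat
}

#' @rdname read_cluster_table
#' @param dat data.frame to write.
#' @export
write_cluster_table <- function(dat, path) {
  atomic_write(path, function(p)
    utils::write.csv(dat, p, row.names = FALSE))
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Estimates, CIs, variance parameters, log-likelihood, AIC, and
#' convergence flags, in a plain machine-readable sidecar.
#'
#' @param fit a [geofit()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  s <- summary(fit)
  payload <- list(
    correlation = fit$correlation,
    coefficients = cbind(term = rownames(s$coefficients),
                         s$coefficients),
    varcomp = cbind(parameter = rownames(s$varcomp), s$varcomp),
    log_likelihood = fit$log_likelihood,
    aic = fit$aic,
    n_individuals = fit$n_individuals,
    n_clusters = fit$n_clusters,
    converged = fit$converged,
    phi_identifiable = fit$phi_identifiable,
    practical_range_km = if (fit$correlation == "exponential")
      practical_range(fit$params$phi) else NULL)
  atomic_write(path, function(p)
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows"))
  invisible(path)
}

#' Build a prediction-grid design from a covariate stack
#'
#' Evaluates the model's covariates at every cell center of the stack's
#' geometry. Monthly covariates enter at the lag encoded in their column
#' name (`"<name>_lag<d>"`): for a given `birth_month` the raster of
#' month `birth_month - d` is used; with `birth_month = NULL` the
#' long-run monthly mean (climatology) is used, i.e. the prediction for a
#' generic child.
#'
#' @param stack a `covariate_stack` (see [sim_covariate_fields()]).
#' @param columns character vector of design column names.
#' @param birth_month reference birth month, or `NULL` for climatology.
#' @param coord_names names for the two coordinate columns (match the
#'   fit's, e.g. `c("x_km", "y_km")`, so the result feeds [predict.geofit()]
#'   directly).
#' @return data.frame with cell-center coordinates (km) and one column
#'   per requested covariate, on the original (unstandardized) scale.
#' @export
grid_design <- function(stack, columns, birth_month = NULL,
                        coord_names = c("x_km", "y_km")) {
  stopifnot(inherits(stack, "covariate_stack") ||
              (is.list(stack) && !is.null(stack$geometry)))
  cc <- raster_cell_centers(stack$geometry)
  out <- stats::setNames(data.frame(cc$x, cc$y), coord_names)
  for (nm in columns) {
    lag <- lag_from_name(nm)
    if (is.na(lag)) {
      r <- stack$constant[[nm]]
      if (is.null(r)) stop("stack lacks constant covariate: ", nm,
                           call. = FALSE)
      out[[nm]] <- as.numeric(extract_at_points(r, cc$x, cc$y))
    } else {
      base <- sub("_lag[0-9]+$", "", nm)
      series <- stack$monthly[[base]]
      if (is.null(series)) stop("stack lacks monthly covariate: ", base,
                                call. = FALSE)
      if (is.null(birth_month)) {
        vals <- rowMeans(vapply(series, function(r)
          as.numeric(extract_at_points(r, cc$x, cc$y)),
          numeric(nrow(cc))))
      } else {
        tm <- birth_month - lag
        if (tm < 1 || tm > length(series))
          stop("month ", tm, " outside the monthly series", call. = FALSE)
        vals <- as.numeric(extract_at_points(series[[tm]], cc$x, cc$y))
      }
      out[[nm]] <- vals
    }
  }
  out
}

#' Run the full synthetic pipeline
#'
#' simulate -> extract -> scan lags -> fit -> predict -> aggregate, each
#' stage writing plain-text outputs, with a JSON manifest (seeds,
#' checksums, per-stage outputs) enabling exact rerun. Any stage failure
#' halts with the stage named.
#'
#' @param config list with components `sim` (a [sim_config()] or
#'   arguments for one), `formula` (base model without the scanned
#'   covariate), `scan_covariate` (monthly covariate name to lag-scan;
#'   `NA` or `"none"` skips the scan; default `"spei"`), `lags` (candidate lags), `threshold` (default -2),
#'   `n_sims`, `grid_cells` (prediction grid is the covariate raster
#'   grid), `polygons` (a [geo_polygons()] or GeoJSON path, or `NULL`
#'   for a single all-domain polygon), `out` (output directory).
#' @param quiet suppress per-stage messages.
#' @return list with the manifest and the in-memory stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  t0 <- Sys.time()
  if (is.null(config$out)) stop("config$out (output dir) is required",
                                call. = FALSE)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim_cfg <- config$sim
  if (!inherits(sim_cfg, "sim_config"))
    sim_cfg <- do.call(sim_config, sim_cfg %||% list())

  # validate the whole config before any stage runs
  known <- sim_cfg$covariates$name
  scan_cov <- config$scan_covariate %||% "spei"
  if (length(scan_cov) != 1 || is.na(scan_cov) || scan_cov == "none")
    scan_cov <- NULL        # NA / "none" skips the lag-scan stage
  if (!is.null(scan_cov) && !scan_cov %in%
        known[sim_cfg$covariates$kind == "monthly"])
    stop("scan_covariate '", scan_cov,
         "' is not a monthly covariate of the simulation config",
         call. = FALSE)
  f_vars <- all.vars(config$formula %||% (z ~ temperature))[-1]
  unknown <- setdiff(sub("_lag[0-9]+$", "", f_vars), known)
  if (length(unknown))
    stop("formula references unknown covariate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.character(config$polygons) && !file.exists(config$polygons))
    stop("polygon file not found: ", config$polygons, call. = FALSE)

  manifest <- list(created = format(t0), seed = sim_cfg$seed,
                   stages = list(), outputs = list())

  say("stage 1/6: simulate survey (seed %d)", sim_cfg$seed)
  sv <- stage("simulate", simulate_survey(sim_cfg, rasters = TRUE))
  f_clusters <- file.path(config$out, "clusters.csv")
  write_cluster_table(sv$data, f_clusters)
  manifest$stages$simulate <- list(n_individuals = nrow(sv$data),
                                   n_clusters = sim_cfg$n_clusters)

  say("stage 2/6: extract covariates")
  # extraction happened at simulation time against the same stack;
  # persist the population raster alongside
  pop <- stage("extract", sim_population_raster(sim_cfg))
  f_pop <- file.path(config$out, "population.asc")
  write_asc(pop, f_pop)

  formula <- config$formula %||% (z ~ temperature)
  lags <- config$lags %||% 1:12

  if (!is.null(scan_cov)) {
    say("stage 3/6: AIC lag scan for '%s'", scan_cov)
    sc <- stage("scan_lags",
                scan_lags(formula, sv$data, sv$monthly[[scan_cov]],
                          covariate = scan_cov, lags = lags, starts = 2))
    f_scan <- file.path(config$out, "lag_scan.csv")
    atomic_write(f_scan, function(p)
      utils::write.csv(sc$table, p, row.names = FALSE))
    sel_col <- paste0(scan_cov, "_lag", sc$selected)
    cl_idx <- match(sv$data$cluster_id, sort(unique(sv$data$cluster_id)))
    sv$data[[sel_col]] <- as.vector(scale(build_lagged_column(
      sv$monthly[[scan_cov]], cl_idx, sv$data$birth_month, sc$selected)))
    formula <- stats::update(formula, paste(". ~ . +", sel_col))
    manifest$stages$scan_lags <- list(covariate = scan_cov,
                                      selected_lag = sc$selected)
  } else {
    say("stage 3/6: lag scan skipped")
    sc <- NULL
  }

  say("stage 4/6: fit geostatistical model")
  fit <- stage("fit", geofit(formula, sv$data, starts = 3))
  f_fit <- file.path(config$out, "fit.json")
  write_fit_json(fit, f_fit)
  manifest$stages$fit <- list(aic = fit$aic,
                              log_likelihood = fit$log_likelihood)

  say("stage 5/6: predict prevalence surface")
  gd_cols <- setdiff(all.vars(formula)[-1], character(0))
  gdesign <- stage("predict_design",
                   grid_design(sv$stack, gd_cols))
  surf <- stage("predict",
                predict(fit, gdesign, type = "prevalence",
                        threshold = config$threshold %||% -2,
                        method = "closed"))
  surf$population <- raster_values(pop)
  surf$cases <- counts_surface(surf$prevalence, surf$population)
  f_surf <- file.path(config$out, "prevalence_surface.csv")
  atomic_write(f_surf, function(p)
    utils::write.csv(surf, p, row.names = FALSE))
  f_prev <- file.path(config$out, "prevalence.asc")
  write_asc(surface_to_raster(surf, sv$stack$geometry, "prevalence"),
            f_prev)

  say("stage 6/6: aggregate to districts")
  polys <- config$polygons
  if (is.character(polys)) polys <- read_geojson_polygons(polys)
  if (is.null(polys)) {
    ex <- sim_cfg$extent
    polys <- geo_polygons(list(domain = rbind(
      c(ex[1], ex[3]), c(ex[2], ex[3]), c(ex[2], ex[4]),
      c(ex[1], ex[4]))))
  }
  distr <- stage("aggregate", aggregate_polygons(surf, polys,
                                                 surf$population))
  f_distr <- file.path(config$out, "district_summary.csv")
  atomic_write(f_distr, function(p)
    utils::write.csv(distr, p, row.names = FALSE))

  outputs <- c(clusters = f_clusters, population = f_pop,
               fit = f_fit, surface = f_surf, prevalence = f_prev,
               districts = f_distr)
  if (!is.null(sc)) outputs["lag_scan"] <- file.path(config$out,
                                                     "lag_scan.csv")
  manifest$outputs <- as.list(outputs)
  manifest$checksums <- as.list(tools::md5sum(unname(outputs)))
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  f_manifest <- file.path(config$out, "manifest.json")
  atomic_write(f_manifest, function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE))
  invisible(list(manifest = manifest, survey = sv, scan = sc, fit = fit,
                 surface = surf, districts = distr))
}
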