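#' Lagged covariate column relative to birth month
#'
#' For each individual, looks up the monthly covariate value at the
#' individual's location in calendar month `birth_month - lag`; lag 0 is
#' the birth month itself. Months are indexed 1..`n_months` into the
#' series.
#'
#' @param monthly matrix of covariate values, locations (clusters) in rows,
#'   months in columns (see [sim_monthly_at_points()] or
#'   [monthly_at_points()]).
#' @param cluster integer row index of each individual's location.
#' @param birth_month integer month index of each individual's birth.
#' @param lag months before birth, in `0:12` typically.
#' @return numeric vector, one value per individual.
#' @export
build_lagged_column <- function(monthly, cluster, birth_month, lag) {
  stopifnot(is.matrix(monthly), length(cluster) == length(birth_month),
            length(lag) == 1L, lag >= 0)
  target <- birth_month - lag
  if (any(target < 1)) {
    earliest <- lag + 1
    stop("lag ", lag, " precedes the series start for some births; ",
         "earliest feasible birth month for this lag is ", earliest,
         call. = FALSE)
  }
  if (any(target > ncol(monthly)))
    stop("birth month beyond the end of the monthly series", call. = FALSE)
  monthly[cbind(cluster, target)]
}

#' Extract a monthly raster series at point locations
#'
#' @param raster_list list of [geo_raster()] ordered by month.
#' @param x,y point coordinates, km.
#' @return matrix points x months, suitable for [build_lagged_column()].
#' @export
monthly_at_points <- function(raster_list, x, y) {
  out <- vapply(raster_list,
                function(r) as.numeric(extract_at_points(r, x, y)),
                numeric(length(x)))
  colnames(out) <- seq_along(raster_list)
  out
}

#' Standardize design columns to mean 0, SD 1
#'
#' Returns the standardized matrix together with the per-column means and
#' SDs so that prediction grids can be transformed with the *training*
#' record rather than re-standardized (which would break the per-1-SD
#' coefficient scale).
#'
#' @param X numeric matrix or data.frame of covariate columns.
#' @return list with `X` (standardized matrix), `center`, `scale`.
#' @export
standardize_design <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  bad <- which(!is.finite(scl) | scl <= 0)
  if (length(bad))
    stop("zero or undefined SD in column(s): ",
         paste(colnames(X)[bad] %||% bad, collapse = ", "), call. = FALSE)
  list(X = scale(X, center = ctr, scale = scl)[, , drop = FALSE],
       center = ctr, scale = scl)
}

#' Apply a stored standardization record to new data
#'
#' @param X new covariate matrix (same columns as the training design).
#' @param record list with `center` and `scale`, as produced by
#'   [standardize_design()].
#' @return standardized matrix.
#' @export
apply_standardization <- function(X, record) {
  X <- as.matrix(X)
  nm <- names(record$center)
  if (!is.null(colnames(X)) && !is.null(nm)) {
    if (!all(nm %in% colnames(X)))
      stop("new data lacks column(s): ",
           paste(setdiff(nm, colnames(X)), collapse = ", "), call. = FALSE)
    X <- X[, nm, drop = FALSE]
  }
  scale(X, center = record$center, scale = record$scale)[, , drop = FALSE]
}

#' Invert a standardization (for round-trip checks)
#' @param Xs standardized matrix.
#' @inheritParams apply_standardization
#' @return matrix on the original scale.
#' @export
destandardize <- function(Xs, record) {
  sweep(sweep(as.matrix(Xs), 2, record$scale, "*"), 2, record$center, "+")
}

#' Choose the SPEI accumulation timescale by correlation with vegetation
#'
#' SPEI is multiscalar: an n-month timescale accumulates the climatic water
#' balance over the previous n months. The working timescale is chosen as
#' the one whose series best tracks vegetation activity: Pearson r between
#' each candidate SPEI series and the vegetation-index series over pooled
#' (location, month) pairs, argmax r, ties broken toward the shorter
#' timescale.
#'
#' @param spei_by_timescale named list of location x month matrices, one
#'   per candidate timescale; names coercible to their timescale in months.
#' @param vegetation location x month matrix on the same layout.
#' @param per_location if `TRUE`, average per-location correlations instead
#'   of pooling all pairs.
#' @return list with `timescale` (numeric, months), `table` (data.frame of
#'   timescale and correlation, sorted by timescale).
#' @export
select_spei_timescale <- function(spei_by_timescale, vegetation,
                                  per_location = FALSE) {
  if (length(spei_by_timescale) < 2)
    stop("need at least two candidate timescales", call. = FALSE)
  ts <- suppressWarnings(as.numeric(names(spei_by_timescale)))
  if (any(is.na(ts)))
    stop("list names must give the timescale in months", call. = FALSE)
  veg <- as.matrix(vegetation)
  r <- vapply(spei_by_timescale, function(sp) {
    sp <- as.matrix(sp)
    ok <- is.finite(sp) & is.finite(veg)
    if (sum(ok) < 3)
      stop("fewer than 3 overlapping (location, month) pairs", call. = FALSE)
    if (per_location) {
      rs <- vapply(seq_len(nrow(sp)), function(i) {
        oki <- ok[i, ]
        if (sum(oki) < 3) return(NA_real_)
        stats::cor(sp[i, oki], veg[i, oki])
      }, numeric(1))
      mean(rs, na.rm = TRUE)
    } else stats::cor(sp[ok], veg[ok])
  }, numeric(1))
  tab <- data.frame(timescale = ts, correlation = unname(r))
  tab <- tab[order(tab$timescale), , drop = FALSE]
  best_r <- max(tab$correlation)
  # shortest timescale among those within tie tolerance of the maximum
  sel <- tab$timescale[tab$correlation >= best_r - 1e-12][1]
  list(timescale = sel, table = tab)
}

#' Pairwise correlation report for covariate redundancy screening
#'
#' Generic replacement for ad hoc redundancy checks (e.g. NDVI vs EVI,
#' elevation vs slope): Pearson correlations between all covariate pairs,
#' flagged above a threshold. Which member of a redundant pair to keep is a
#' configuration choice, not a rule.
#'
#' @param X covariate matrix/data.frame.
#' @param threshold absolute correlation above which a pair is flagged.
#' @return data.frame `var1`, `var2`, `r`, `flagged`, sorted by |r|.
#' @export
covariate_correlation_report <- function(X, threshold = 0.9) {
  X <- as.matrix(X)
  C <- stats::cor(X, use = "pairwise.complete.obs")
  idx <- which(upper.tri(C), arr.ind = TRUE)
  out <- data.frame(var1 = colnames(C)[idx[, 1]],
                    var2 = colnames(C)[idx[, 2]],
                    r = C[idx])
  out$flagged <- abs(out$r) > threshold
  out[order(-abs(out$r)), , drop = FALSE]
}
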