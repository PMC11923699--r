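#' Scan candidate lags of a monthly covariate by AIC
#'
#' For each candidate lag `d`, the covariate value at the individual's
#' location `d` months before birth is standardized, substituted into the
#' model (the other covariates in `formula` held fixed), and the model
#' refitted; lags are compared by AIC and the argmin selected, ties (AIC
#' difference below `tie_tol`) broken toward the shorter lag. Each lag is
#' tested on its own because columns at neighbouring lags are highly
#' correlated; testing them jointly invites spurious attribution.
#'
#' @param formula base model *without* the scanned covariate, e.g.
#'   `z ~ temperature`.
#' @param data per-individual data.frame (must contain the birth-month
#'   column and the coordinate/cluster columns).
#' @param monthly cluster x month matrix of the scanned covariate (see
#'   [build_lagged_column()]); rows ordered by sorted cluster id.
#' @param covariate name used for the constructed columns
#'   (`"<covariate>_lag<d>"`).
#' @param lags integer candidate lags, subset of `0:12`.
#' @param birth_month name of the birth-month column in `data`.
#' @param tie_tol AIC difference treated as a tie.
#' @param ... passed to [geofit()] (`coords`, `cluster`, `starts`, ...).
#'   Fits after the first are warm-started from the first lag's variance
#'   parameters with a single optimizer start unless overridden.
#' @return object of class `"lag_scan"`: `table` (per lag: `aic`,
#'   `beta`, `se`, `lower`, `upper`, `p`, `converged`, `failed`),
#'   `selected` (lag attaining the minimum AIC), `covariate`, `fits`
#'   (the selected lag's fit).
#' @export
scan_lags <- function(formula, data, monthly, covariate, lags = 1:12,
                      birth_month = "birth_month", tie_tol = 1e-6, ...) {
  stopifnot(is.matrix(monthly), all(lags >= 0), all(lags <= 12),
            !anyDuplicated(lags))
  if (!birth_month %in% names(data))
    stop("data lacks birth-month column '", birth_month, "'",
         call. = FALSE)
  dots <- list(...)
  cluster_f <- dots$cluster %||% (~ cluster_id)
  gvar <- all.vars(cluster_f)
  cl_idx <- match(data[[gvar]], sort(unique(data[[gvar]])))

  lags <- sort(lags)
  rows <- vector("list", length(lags))
  best_fit <- NULL; warm <- NULL
  for (i in seq_along(lags)) {
    d <- lags[i]
    colname <- paste0(covariate, "_lag", d)
    res <- tryCatch({
      col <- build_lagged_column(monthly, cl_idx, data[[birth_month]], d)
      dat_d <- data
      dat_d[[colname]] <- as.vector(scale(col))
      f_d <- stats::update(formula,
                           paste(". ~ . +", colname))
      args <- c(list(formula = f_d, data = dat_d), dots)
      if (!is.null(warm) && is.null(dots$init)) {
        args$init <- warm
        args$starts <- 1      # dispersal is pointless around a warm start
      }
      if (is.null(args$check_phi)) args$check_phi <- FALSE
      fit <- do.call(geofit, args)
      s <- summary(fit)$coefficients[colname, ]
      list(fit = fit,
           row = data.frame(lag = d, aic = fit$aic, beta = s$estimate,
                            se = s$se, lower = s$lower, upper = s$upper,
                            p = s$p, converged = fit$converged,
                            failed = FALSE))
    }, error = function(e) {
      list(fit = NULL,
           row = data.frame(lag = d, aic = NA_real_, beta = NA_real_,
                            se = NA_real_, lower = NA_real_,
                            upper = NA_real_, p = NA_real_,
                            converged = FALSE, failed = TRUE,
                            row.names = NULL),
           err = conditionMessage(e))
    })
    rows[[i]] <- res$row
    if (!is.null(res$fit)) {
      warm <- list(sigma2 = res$fit$params$sigma2,
                   phi = res$fit$params$phi,
                   omega2 = res$fit$params$omega2)
      if (is.null(best_fit) || res$fit$aic < best_fit$aic - tie_tol)
        best_fit <- res$fit
    }
  }
  tab <- do.call(rbind, rows)
  if (all(tab$failed))
    stop("every candidate lag failed to fit", call. = FALSE)
  ok <- !tab$failed
  min_aic <- min(tab$aic[ok])
  # shortest lag among ties
  selected <- tab$lag[ok][tab$aic[ok] <= min_aic + tie_tol][1]
  sel_fit <- if (!is.null(best_fit) &&
                 abs(best_fit$aic - min_aic) <= tie_tol) best_fit else NULL
  structure(list(table = tab, selected = selected, covariate = covariate,
                 fit = sel_fit,
                 n_failed = sum(tab$failed)),
            class = "lag_scan")
}

#' @export
print.lag_scan <- function(x, digits = 4, ...) {
  cat(sprintf("AIC scan over %d lag(s) of '%s'\n", nrow(x$table),
              x$covariate))
  print(round(x$table[, c("lag", "aic", "beta", "lower", "upper", "p")],
              digits))
  cat(sprintf("Selected lag: %d months before birth\n", x$selected))
  if (x$n_failed)
    cat(sprintf("(%d lag(s) failed to fit and were skipped)\n",
                x$n_failed))
  invisible(x)
}
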