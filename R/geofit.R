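#' Fit the linear geostatistical model by maximum likelihood
#'
#' Fits \eqn{Y_{ij} = \alpha + \beta^T D(x_i) + S(x_i) + U_{ij}} to
#' continuous z-scores observed on individuals grouped in GPS-located
#' clusters: \eqn{S} a stationary Gaussian process with exponential
#' correlation \eqn{\exp(-u/\phi)} and variance \eqn{\sigma^2}, \eqn{U}
#' iid Gaussian nugget with variance \eqn{\omega^2}. Because the model is
#' linear-Gaussian the marginal likelihood is available in closed form and
#' is maximized exactly (no Monte Carlo), over
#' \eqn{(\log\sigma^2, \log\phi, \log\omega^2)} with the regression
#' coefficients profiled out by generalized least squares.
#'
#' Confidence intervals use the observed information of the profile
#' likelihood: variance parameters on the log scale and back-transformed
#' (hence asymmetric), coefficients from the GLS covariance at the
#' maximum. Optimization restarts from several dispersed,
#' variogram-informed starting points because the likelihood in
#' \eqn{\phi} can be flat or multimodal; if the profile likelihood over
#' \eqn{\phi} is flat (varies by less than `phi_flat_tol` across two
#' orders of magnitude) the scale is reported as non-identifiable and a
#' compound-symmetry fallback (iid cluster effects; the no-spatial-
#' correlation limit) is fitted for comparison.
#'
#' @param formula model formula for the outcome and covariates, e.g.
#'   `haz ~ temperature + spei_lag3`.
#' @param data data.frame with one row per individual.
#' @param coords one-sided formula naming the coordinate columns in km
#'   (default `~ x_km + y_km`).
#' @param cluster one-sided formula naming the cluster id column
#'   (default `~ cluster_id`).
#' @param correlation `"exponential"` for the spatial model,
#'   `"independent"` for the compound-symmetry (non-spatial) variant.
#' @param standardize standardize covariate columns to mean 0 / SD 1
#'   before fitting (coefficients then read "per 1 SD"); the record is
#'   stored and reapplied to prediction grids. Columns already
#'   standardized are unchanged up to numerical noise.
#' @param starts number of dispersed optimizer starts.
#' @param init optional list with elements among `sigma2`, `phi`,
#'   `omega2` used as the first start (e.g. warm starts in lag scans).
#' @param check_phi run the profile-flatness identifiability check (adds
#'   a handful of 2-parameter optimizations).
#' @param phi_flat_tol flatness threshold for the profile log-likelihood.
#' @return An object of class `"geofit"`; see [summary.geofit()],
#'   [predict.geofit()], [simulate.geofit()], [residuals.geofit()].
#' @examples
#' sv <- simulate_survey(sim_config(n_clusters = 60, seed = 7))
#' fit <- geofit(z ~ temperature + spei_lag3, data = sv$data, starts = 2)
#' summary(fit)
#' @export
geofit <- function(formula, data,
                   coords = ~ x_km + y_km,
                   cluster = ~ cluster_id,
                   correlation = c("exponential", "independent"),
                   standardize = TRUE,
                   starts = 5,
                   init = NULL,
                   check_phi = TRUE,
                   phi_flat_tol = 0.01) {
  correlation <- match.arg(correlation)
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  trms <- attr(mf, "terms")
  X <- stats::model.matrix(trms, mf)
  cvars <- all.vars(coords)
  gvar <- all.vars(cluster)
  stopifnot(length(cvars) == 2, length(gvar) == 1)
  miss <- setdiff(c(cvars, gvar), names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  keep <- stats::complete.cases(X) & is.finite(y) &
    is.finite(data[[cvars[1]]]) & is.finite(data[[cvars[2]]])
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " row(s) with missing values excluded from fitting")
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  xy <- cbind(data[[cvars[1]]], data[[cvars[2]]])[keep, , drop = FALSE]
  cid <- data[[gvar]][keep]

  std_record <- NULL
  if (standardize) {
    covcols <- setdiff(colnames(X), "(Intercept)")
    covcols <- covcols[apply(X[, covcols, drop = FALSE], 2,
                             function(v) stats::sd(v) > 0)]
    if (length(covcols)) {
      sd0 <- standardize_design(X[, covcols, drop = FALSE])
      X[, covcols] <- sd0$X
      std_record <- list(center = sd0$center, scale = sd0$scale)
    }
  }

  # collapse to cluster-level coordinates
  ucl <- sort(unique(cid))
  cl_idx <- match(cid, ucl)
  coords_m <- rowsum(xy, cl_idx, reorder = TRUE) /
    as.vector(table(cl_idx))
  if (nrow(coords_m) < 2) stop("need at least 2 clusters", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  gd <- geo_data(y, X, coords_m, cl_idx)

  spatial <- correlation == "exponential"
  # optimize the concentrated likelihood: (variance ratio, range) only,
  # total variance and coefficients profiled out in closed form
  th0 <- start_values2(gd, spatial, starts, init)
  best <- NULL
  for (s in seq_len(nrow(th0))) {
    o <- if (spatial)
      stats::optim(th0[s, ], function(th)
        -profile_loglik2(gd, th, TRUE)$value,
        method = "Nelder-Mead",
        control = list(maxit = 400, reltol = 1e-9))
    else
      stats::optim(th0[s, 1], function(th)
        -profile_loglik2(gd, th, FALSE)$value,
        method = "Brent", lower = -18, upper = 18)
    if (is.null(best) || o$value < best$value) best <- o
  }
  converged <- best$convergence == 0 && is.finite(best$value)
  pl <- profile_loglik2(gd, best$par, spatial)
  ll <- pl$value
  theta <- if (spatial) log(c(pl$sigma2, pl$phi, pl$omega2))
           else log(c(pl$sigma2, pl$omega2))

  # observed information: profile-likelihood Hessian over theta,
  # GLS covariance for the regression coefficients
  H <- tryCatch(stats::optimHess(theta, function(th)
    -profile_loglik(gd, th, spatial)$value), error = function(e) NULL)
  theta_vcov <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  if (!is.null(theta_vcov) && any(diag(theta_vcov) < 0)) theta_vcov <- NULL
  vcov_beta <- solve(pl$XtSiX)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  k <- gd$p + if (spatial) 3L else 2L
  aic <- 2 * k - 2 * ll

  names(pl$beta) <- colnames(X)
  has_int <- "(Intercept)" %in% colnames(X)
  alpha <- if (has_int) pl$beta[["(Intercept)"]] else 0
  beta_cov <- pl$beta[setdiff(colnames(X), "(Intercept)")]
  params <- geo_params(alpha = alpha, beta = beta_cov,
                       sigma2 = pl$sigma2,
                       phi = if (spatial) pl$phi else 1e-6,
                       omega2 = pl$omega2)

  fit <- structure(list(
    call = cl, formula = formula, terms = trms,
    correlation = correlation,
    coefficients = pl$beta, vcov = vcov_beta,
    params = params, theta = theta, theta_vcov = theta_vcov,
    log_likelihood = ll, aic = aic, k = k,
    n_individuals = gd$n, n_clusters = gd$m, n_dropped = n_dropped,
    gd = gd, std_record = std_record, converged = converged,
    coord_names = cvars, cluster_name = gvar,
    cluster_levels = ucl,
    phi_identifiable = NA, phi_profile = NULL, nonspatial = NULL),
    class = "geofit")

  if (spatial && check_phi) {
    prof <- profile_phi(fit)
    fit$phi_profile <- prof
    fit$phi_identifiable <- diff(range(prof$loglik)) >= phi_flat_tol
    if (!fit$phi_identifiable) {
      warning("phi is not identifiable (flat profile likelihood); ",
              "fitting the non-spatial compound-symmetry fallback",
              call. = FALSE)
      fit$nonspatial <- geofit(formula, data, coords = coords,
                               cluster = cluster,
                               correlation = "independent",
                               standardize = standardize, starts = starts,
                               check_phi = FALSE)
    }
  } else if (spatial) fit$phi_identifiable <- TRUE
  fit
}

# dispersed, variogram-informed starting values for the concentrated
# parameterization (qlogis(variance ratio), log(range))
start_values2 <- function(gd, spatial, starts, init = NULL) {
  b0 <- tryCatch(qr.solve(gd$X, gd$y), error = function(e) rep(0, gd$p))
  r <- gd$y - as.vector(gd$X %*% b0)
  # within-cluster variance -> nugget; cluster-mean variance -> sill
  rbar <- as.vector(rowsum(r, gd$cluster) / gd$n_i[gd$n_i > 0])
  within <- sum((r - rbar[gd$cluster])^2) / max(gd$n - gd$m, 1)
  om0 <- max(within, 1e-4)
  sg0 <- max(stats::var(rbar) - om0 / mean(gd$n_i[gd$n_i > 0]),
             0.05 * om0)
  ph0 <- max(pair_dist(gd$coords)) / 10
  if (!is.null(init)) {
    sg0 <- init$sigma2 %||% sg0
    ph0 <- init$phi %||% ph0
    om0 <- init$omega2 %||% om0
  }
  base <- c(stats::qlogis(sg0 / (sg0 + om0)), log(ph0))
  disp <- list(c(0, 0), c(1, -1.5), c(-1, 1.5), c(2, -3), c(-2, 3))
  th <- t(vapply(disp[seq_len(min(max(starts, 1), 5))],
                 function(d) base + d, numeric(2)))
  matrix(th, ncol = 2)
}

#' Profile log-likelihood over the spatial scale phi
#'
#' Re-maximizes the likelihood over \eqn{(\sigma^2, \omega^2)} on a log-
#' spaced grid of \eqn{\phi} spanning two orders of magnitude around the
#' estimate. A flat profile signals that the data cannot distinguish
#' spatial correlation ranges, the situation in which the spatial term
#' degenerates to iid cluster effects.
#'
#' @param fit a spatial [geofit()].
#' @param span half-width factor of the grid (default 10: phi-hat/10 to
#'   phi-hat*10).
#' @param n grid size.
#' @return data.frame `phi`, `loglik`.
#' @export
profile_phi <- function(fit, span = 10, n = 7) {
  stopifnot(inherits(fit, "geofit"), fit$correlation == "exponential")
  gd <- fit$gd
  phis <- exp(seq(log(fit$params$phi / span), log(fit$params$phi * span),
                  length.out = n))
  ll <- vapply(phis, function(ph) {
    o <- stats::optim(0, function(q)
      -profile_loglik2(gd, c(q, log(ph)), TRUE)$value,
      method = "Brent", lower = -18, upper = 18)
    -o$value
  }, numeric(1))
  data.frame(phi = phis, loglik = ll)
}

#' @export
print.geofit <- function(x, digits = 4, ...) {
  cat("Linear geostatistical model (",
      if (x$correlation == "exponential") "exponential spatial correlation"
      else "independent cluster effects", ")\n", sep = "")
  cat(sprintf("  %d individuals in %d clusters; logLik %.3f; AIC %.3f\n",
              x$n_individuals, x$n_clusters, x$log_likelihood, x$aic))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("sigma2 = %.4g, %somega2 = %.4g\n",
              x$params$sigma2,
              if (x$correlation == "exponential")
                sprintf("phi = %.4g km (practical range %.4g km), ",
                        x$params$phi, practical_range(x$params$phi))
              else "",
              x$params$omega2))
  if (isFALSE(x$phi_identifiable))
    cat("NOTE: phi not identifiable (flat profile likelihood);",
        "see $nonspatial fallback\n")
  invisible(x)
}

#' Summarize a fitted geostatistical model
#'
#' Coefficient table with Wald 95% CIs and two-sided p-values, and
#' variance parameters with asymmetric CIs back-transformed from the log
#' scale.
#'
#' @param object a [geofit()].
#' @param level confidence level.
#' @param ... unused.
#' @return object of class `"summary.geofit"` with elements
#'   `coefficients` (est/se/ci/p), `varcomp` (est/ci), and fit metadata.
#' @export
summary.geofit <- function(object, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(object$vcov))
  est <- object$coefficients
  zstat <- est / se
  ctab <- data.frame(estimate = est, se = se,
                     lower = est - zq * se, upper = est + zq * se,
                     z = zstat,
                     p = 2 * stats::pnorm(-abs(zstat)))
  vn <- if (object$correlation == "exponential")
    c("sigma2", "phi", "omega2") else c("sigma2", "omega2")
  vest <- exp(object$theta)
  if (!is.null(object$theta_vcov)) {
    vse <- sqrt(diag(object$theta_vcov))
    vtab <- data.frame(estimate = vest,
                       lower = exp(object$theta - zq * vse),
                       upper = exp(object$theta + zq * vse),
                       row.names = vn)
  } else {
    vtab <- data.frame(estimate = vest, lower = NA_real_, upper = NA_real_,
                       row.names = vn)
  }
  structure(list(coefficients = ctab, varcomp = vtab,
                 log_likelihood = object$log_likelihood, aic = object$aic,
                 n_individuals = object$n_individuals,
                 n_clusters = object$n_clusters,
                 correlation = object$correlation,
                 phi_identifiable = object$phi_identifiable,
                 converged = object$converged, level = level),
            class = "summary.geofit")
}

#' @export
print.summary.geofit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear geostatistical model: %d individuals, %d clusters\n",
              x$n_individuals, x$n_clusters))
  cat(sprintf("logLik %.3f   AIC %.3f   (%s correlation)\n",
              x$log_likelihood, x$aic, x$correlation))
  cat("\nCoefficients (per 1 SD for standardized covariates):\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nVariance parameters (%.0f%% CI, log-scale Wald):\n",
              100 * x$level))
  print(round(x$varcomp, digits))
  if (isFALSE(x$phi_identifiable))
    cat("\nNOTE: phi not identifiable; non-spatial fallback fitted.\n")
  if (!x$converged) cat("\nWARNING: optimizer did not report convergence.\n")
  invisible(x)
}

#' @export
coef.geofit <- function(object, ...) object$coefficients

#' @export
vcov.geofit <- function(object, ...) object$vcov

#' @export
logLik.geofit <- function(object, ...) {
  structure(object$log_likelihood, df = object$k,
            nobs = object$n_individuals, class = "logLik")
}

#' Confidence intervals for a fitted geostatistical model
#'
#' @param object a [geofit()].
#' @param parm coefficients and/or variance-parameter names (default all).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with lower/upper columns; variance parameters
#'   (`sigma2`, `phi`, `omega2`) get log-scale Wald intervals.
#' @export
confint.geofit <- function(object, parm = NULL, level = 0.95, ...) {
  s <- summary(object, level = level)
  ci <- rbind(as.matrix(s$coefficients[, c("lower", "upper")]),
              as.matrix(s$varcomp[, c("lower", "upper")]))
  colnames(ci) <- paste0(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2)), " %")
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Residuals of a fitted geostatistical model
#'
#' @param object a [geofit()].
#' @param type `"response"` for individual-level residuals
#'   `y - alpha - X beta`, or `"cluster"` for cluster-mean residuals
#'   (the carrier of residual spatial signal used by the variogram).
#' @param ... unused.
#' @return numeric vector; for `"cluster"` with names = cluster ids and
#'   attribute `"coords"`.
#' @export
residuals.geofit <- function(object, type = c("response", "cluster"), ...) {
  type <- match.arg(type)
  gd <- object$gd
  r <- gd$y - as.vector(gd$X %*% object$coefficients)
  if (type == "response") return(r)
  rbar <- as.vector(rowsum(r, gd$cluster) / gd$n_i[gd$n_i > 0])
  names(rbar) <- object$cluster_levels
  attr(rbar, "coords") <- gd$coords
  rbar
}

#' Simulate outcomes from a fitted geostatistical model
#'
#' Unconditional draws of new z-scores at the observed design and cluster
#' locations (fresh spatial field + fresh nugget), the parametric-
#' bootstrap generator.
#'
#' @param object a [geofit()].
#' @param nsim number of replicate outcome vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns `sim_1..sim_nsim`.
#' @export
simulate.geofit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gd <- object$gd
  mu <- as.vector(gd$X %*% object$coefficients)
  p <- object$params
  sims <- matrix(NA_real_, gd$n, nsim)
  spatial <- object$correlation == "exponential"
  if (p$sigma2 > 0) {
    Cs <- if (spatial) p$sigma2 * exp(-gd$U / p$phi)
          else diag(p$sigma2, gd$m)
    cS <- chol_jitter(Cs)
  }
  for (s in seq_len(nsim)) {
    S <- if (p$sigma2 > 0)
      as.vector(crossprod(cS, stats::rnorm(gd$m))) else rep(0, gd$m)
    sims[, s] <- mu + S[gd$cluster] +
      stats::rnorm(gd$n, 0, sqrt(p$omega2))
  }
  stats::setNames(as.data.frame(sims), paste0("sim_", seq_len(nsim)))
}

#' @export
plot.geofit <- function(x, bins = 12, ...) {
  r <- residuals(x, type = "cluster")
  vg <- empirical_variogram(r, attr(r, "coords"), bins = bins)
  plot(vg, ...)
  if (x$correlation == "exponential") {
    p <- x$params
    m <- mean(x$gd$n_i)
    curve(p$sigma2 * (1 - exp(-u / p$phi)) + p$omega2 / m, xname = "u",
          from = 0, to = max(vg$table$mid, na.rm = TRUE),
          add = TRUE, col = "firebrick", lwd = 2)
  }
  invisible(x)
}
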