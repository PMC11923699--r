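#' Kriging distribution of the latent spatial process
#'
#' Conditional (plug-in) Gaussian distribution of `S` at new locations
#' given the observed cluster data, with the MLEs treated as known.
#' Conditioning is on cluster-mean residuals, which are sufficient for
#' `S` under the model: the kriging mean is `c(x)' Sigma^-1 (ybar - mu)`
#' and the variance `sigma2 - c(x)' Sigma^-1 c(x)`, where `Sigma` is the
#' cluster-mean covariance `sigma2 R + diag(omega2 / n_i)`.
#'
#' For a non-spatial (compound symmetry) fit the cluster effects carry no
#' information to unobserved locations: mean 0 and variance `sigma2`.
#'
#' @param fit a [geofit()].
#' @param new_coords matrix/data.frame of prediction locations, km.
#' @param joint if `TRUE`, also return the joint conditional covariance
#'   matrix (needed for conditional simulation; G x G, so keep G modest).
#' @return list with `mean`, `var` (per location; `var` in
#'   `[0, sigma2]`), and optionally `cov`.
#' @export
krige_latent <- function(fit, new_coords, joint = FALSE) {
  stopifnot(inherits(fit, "geofit"))
  new_coords <- as.matrix(new_coords)
  G <- nrow(new_coords)
  p <- fit$params
  if (fit$correlation != "exponential" || p$sigma2 < 1e-12) {
    out <- list(mean = rep(0, G), var = rep(p$sigma2, G))
    if (joint) out$cov <- diag(p$sigma2, G)
    return(out)
  }
  gd <- fit$gd
  rbar <- as.vector(rowsum(gd$y - as.vector(gd$X %*% fit$coefficients),
                           gd$cluster) / gd$n_i[gd$n_i > 0])
  Sig <- p$sigma2 * exp(-gd$U / p$phi) + diag(p$omega2 / gd$n_i)
  cS <- tryCatch(chol_jitter(Sig, jitter = 0), error = function(e)
    stop("cluster covariance is singular even after jitter; sigma2 = ",
         p$sigma2, ", omega2 = ", p$omega2, call. = FALSE))
  Cg <- p$sigma2 * exp(-pair_dist(new_coords, gd$coords) / p$phi)  # G x m
  W <- backsolve(cS, forwardsolve(t(cS), t(Cg)))                   # m x G
  mean_g <- as.vector(Cg %*% backsolve(cS, forwardsolve(t(cS), rbar)))
  var_g <- pmax(p$sigma2 - colSums(t(Cg) * W), 0)
  out <- list(mean = mean_g, var = var_g)
  if (joint) {
    Rgg <- exp(-pair_dist(new_coords) / p$phi)
    out$cov <- p$sigma2 * Rgg - Cg %*% W
    out$cov <- (out$cov + t(out$cov)) / 2
  }
  out
}

#' Predict z-score distributions and prevalence on new locations
#'
#' For each prediction location (typically grid-cell centers), returns the
#' predictive mean of `alpha + beta' D(x) + S(x)`, its kriging SD, and --
#' for `type = "prevalence"` -- the probability that a new individual's
#' z-score falls below `threshold`,
#' `P(Y < t) = Phi((t - m(x)) / sqrt(v(x) + omega2))`, i.e. prevalence of
#' stunting/underweight/wasting at `t = -2`. The closed form is exact
#' under the Gaussian model; `method = "simulation"` instead averages the
#' nugget-conditional probability over joint draws of `S`, which agrees
#' with the closed form within Monte Carlo error and additionally
#' supports nonlinear functionals of jointly dependent cells.
#'
#' Covariates in `newdata` must be on the original scale; the training
#' standardization record is applied internally (never re-standardized on
#' the grid). Rows with non-finite covariates are masked (`NA`) and
#' counted in the `"n_masked"` attribute.
#'
#' @param object a [geofit()].
#' @param newdata data.frame with the model's covariate columns plus the
#'   coordinate columns used at fit time.
#' @param type `"latent"` (S only), `"response"` (predictive mean/SD of a
#'   new individual's z-score) or `"prevalence"`.
#' @param threshold z-score cutoff (default -2).
#' @param method closed form or conditional simulation (prevalence only).
#' @param n_sims draws for the simulation path (>= 500).
#' @param seed seed for the simulation path.
#' @param ... unused.
#' @return data.frame with coordinates, `mean`, `sd`, and for prevalence
#'   a `prevalence` column; class `"geo_surface"`.
#' @export
predict.geofit <- function(object, newdata,
                           type = c("prevalence", "response", "latent"),
                           threshold = -2,
                           method = c("closed", "simulation"),
                           n_sims = 1000, seed = NULL, ...) {
  type <- match.arg(type)
  method <- match.arg(method)
  cvars <- object$coord_names
  if (!all(cvars %in% names(newdata)))
    stop("newdata lacks coordinate column(s): ",
         paste(setdiff(cvars, names(newdata)), collapse = ", "),
         call. = FALSE)
  xy <- as.matrix(newdata[, cvars])

  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.pass)
  X <- stats::model.matrix(tt, mf)
  if (!is.null(object$std_record)) {
    nm <- names(object$std_record$center)
    X[, nm] <- apply_standardization(X[, nm, drop = FALSE],
                                     object$std_record)
  }
  masked <- !stats::complete.cases(X) | !is.finite(xy[, 1]) |
    !is.finite(xy[, 2])
  out <- data.frame(newdata[, cvars, drop = FALSE])
  ok <- which(!masked)
  if (!length(ok)) stop("all prediction rows are masked", call. = FALSE)

  if (type == "latent") {
    kr <- krige_latent(object, xy[ok, , drop = FALSE])
    out$mean <- out$sd <- NA_real_
    out$mean[ok] <- kr$mean
    out$sd[ok] <- sqrt(kr$var)
  } else {
    p <- object$params
    need_joint <- type == "prevalence" && method == "simulation"
    kr <- krige_latent(object, xy[ok, , drop = FALSE], joint = need_joint)
    mu <- as.vector(X[ok, , drop = FALSE] %*% object$coefficients) +
      kr$mean
    out$mean <- out$sd <- NA_real_
    out$mean[ok] <- mu
    out$sd[ok] <- sqrt(kr$var + if (type == "response") p$omega2 else 0)
    if (type == "prevalence") {
      out$sd[ok] <- sqrt(kr$var)
      out$prevalence <- NA_real_
      if (method == "closed") {
        out$prevalence[ok] <-
          stats::pnorm((threshold - mu) / sqrt(kr$var + p$omega2))
      } else {
        if (n_sims < 500)
          stop("simulation path requires n_sims >= 500", call. = FALSE)
        if (!is.null(seed)) set.seed(seed)
        draws <- rmvn(n_sims, kr$mean, kr$cov)       # G x n_sims
        mu_fix <- as.vector(X[ok, , drop = FALSE] %*%
                              object$coefficients)
        om <- sqrt(p$omega2)
        pr <- rowMeans(stats::pnorm((threshold - mu_fix - draws) / om))
        out$prevalence[ok] <- pr
      }
    }
  }
  attr(out, "n_masked") <- sum(masked)
  attr(out, "threshold") <- if (type == "prevalence") threshold else NULL
  attr(out, "n_sims") <- if (type == "prevalence" &&
                             method == "simulation") n_sims else NULL
  class(out) <- c("geo_surface", class(out))
  out
}

#' Expected case counts from a prevalence surface
#'
#' Cellwise product of prevalence and under-5 population. Masked
#' (NA) prevalence cells propagate to NA counts.
#'
#' @param prevalence a [geo_raster()] of prevalence, or a numeric vector.
#' @param population a [geo_raster()] of counts on the same geometry, or a
#'   numeric vector of the same length.
#' @return same container as the inputs (raster or vector) of expected
#'   cases, `0 <= cases <= population`.
#' @export
counts_surface <- function(prevalence, population) {
  if (inherits(prevalence, "geo_raster") &&
      inherits(population, "geo_raster")) {
    if (!same_geometry(prevalence, population))
      stop("prevalence and population rasters have different geometries",
           call. = FALSE)
    out <- prevalence
    out$values <- prevalence$values * population$values
    return(out)
  }
  if (length(prevalence) != length(population))
    stop("prevalence and population lengths differ", call. = FALSE)
  prevalence * population
}

#' Rasterize a predicted surface column
#'
#' @param surface a `geo_surface` data.frame from [predict.geofit()] whose
#'   rows are the cell centers of `geometry` (any order).
#' @param geometry a [geo_raster()] supplying the target grid.
#' @param column which column to rasterize.
#' @return a [geo_raster()].
#' @export
surface_to_raster <- function(surface, geometry, column = "prevalence") {
  cc <- raster_cell_centers(geometry)
  key <- function(x, y) paste(round(x, 6), round(y, 6))
  idx <- match(key(cc$x, cc$y),
               key(surface[[1]], surface[[2]]))
  if (anyNA(idx))
    stop("surface rows do not cover every cell of the geometry",
         call. = FALSE)
  out <- geometry
  out$values <- matrix(surface[[column]][idx], nrow(geometry$values),
                       ncol(geometry$values), byrow = TRUE)
  out
}
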