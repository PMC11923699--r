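#' Parameters of the linear geostatistical model
#'
#' Bundles the parameters of the model
#' \deqn{Y_{ij} = \alpha + \beta^T D(x_i) + S(x_i) + U_{ij},}
#' where \eqn{S} is a stationary isotropic Gaussian process with variance
#' \eqn{\sigma^2} and exponential correlation \eqn{\exp(-u/\phi)}
#' (\eqn{u} = Euclidean distance in km), and \eqn{U_{ij}} are iid
#' \eqn{N(0, \omega^2)} individual-level (nugget) effects.
#'
#' @param alpha intercept, in z-score units.
#' @param beta named numeric vector of coefficients for (standardized)
#'   covariates, z-score units per 1 SD. May be empty.
#' @param sigma2 spatial (between-cluster) variance \eqn{\sigma^2 \ge 0}.
#' @param phi correlation scale \eqn{\phi > 0}, km.
#' @param omega2 nugget (individual residual) variance \eqn{\omega^2 \ge 0}.
#' @return An object of class `"geo_params"`.
#' @examples
#' geo_params(alpha = -1.23, sigma2 = 0.15, phi = 18.28, omega2 = 2.02)
#' @export
geo_params <- function(alpha = 0, beta = numeric(0), sigma2 = 1,
                       phi = 1, omega2 = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta))
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 < 0)
    stop("'sigma2' must be a single finite value >= 0", call. = FALSE)
  if (!is.numeric(omega2) || length(omega2) != 1L || !is.finite(omega2) ||
      omega2 < 0)
    stop("'omega2' must be a single finite value >= 0", call. = FALSE)
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("'phi' must be a single finite value > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, sigma2 = sigma2,
                 phi = phi, omega2 = omega2),
            class = "geo_params")
}

#' @export
print.geo_params <- function(x, digits = 4, ...) {
  cat("Linear geostatistical model parameters\n")
  cat("  intercept alpha :", format(x$alpha, digits = digits), "\n")
  if (length(x$beta)) {
    cat("  coefficients beta (per 1 SD):\n")
    print(round(x$beta, digits))
  }
  cat("  spatial variance sigma^2 :", format(x$sigma2, digits = digits), "\n")
  cat("  scale phi (km)           :", format(x$phi, digits = digits),
      " [practical range ", format(practical_range(x$phi), digits = digits),
      " km]\n", sep = "")
  cat("  nugget omega^2           :", format(x$omega2, digits = digits), "\n")
  invisible(x)
}

#' Exponential spatial correlation function
#'
#' \eqn{\rho(u) = \exp(-u/\phi)}: correlation between the latent spatial
#' process at two locations a Euclidean distance `u` km apart.
#'
#' @param u distance(s), km; must be >= 0.
#' @param phi scale parameter, km; > 0.
#' @return Correlation in (0, 1]; 1 at `u = 0`, strictly decreasing in `u`.
#' @examples
#' exp_correlation(0, 18.28)            # 1
#' exp_correlation(3 * 18.28, 18.28)    # ~0.05 at the practical range
#' @export
exp_correlation <- function(u, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("'phi' must be a single finite value > 0", call. = FALSE)
  if (any(!is.finite(u)) || any(u < 0))
    stop("distances 'u' must be finite and >= 0", call. = FALSE)
  exp(-u / phi)
}

#' Practical range of the exponential correlation
#'
#' The distance at which spatial correlation has decayed to 0.05. For the
#' exponential model this is conventionally approximated as \eqn{3\phi}
#' (the exact value is \eqn{-\phi \log 0.05 \approx 2.996\phi}).
#'
#' @param phi scale parameter, km; > 0.
#' @param exact if `TRUE`, return the exact \eqn{-\phi\log(0.05)} instead of
#'   the conventional `3 * phi`.
#' @return Distance in km.
#' @examples
#' practical_range(18.28)   # 54.84 km
#' practical_range(32.17)   # 96.51 km
#' @export
practical_range <- function(phi, exact = FALSE) {
  if (!is.numeric(phi) || any(!is.finite(phi)) || any(phi <= 0))
    stop("'phi' must be finite and > 0", call. = FALSE)
  if (exact) -phi * log(0.05) else 3 * phi
}
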