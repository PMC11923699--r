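#' Implied covariance matrix between individuals
#'
#' Under the model, the covariance between individual `j` at cluster `i`
#' and individual `j'` at cluster `i'` is
#' `sigma2 * exp(-u_{ii'}/phi) + omega2 * 1[i = i', j = j']`: individuals
#' sharing a cluster share the full spatial variance (distance 0), and the
#' nugget sits on the diagonal only.
#'
#' @param coords matrix/data.frame of cluster coordinates (km), one row per
#'   cluster.
#' @param cluster integer cluster index per individual.
#' @param params a [geo_params()].
#' @return dense n x n covariance matrix (n = individuals). Intended for
#'   small problems and as the reference the blocked likelihood is tested
#'   against; the fitting path never forms it.
#' @export
build_covariance <- function(coords, cluster, params) {
  stopifnot(inherits(params, "geo_params"))
  coords <- as.matrix(coords)
  if (any(cluster < 1 | cluster > nrow(coords)))
    stop("every individual must map to a cluster", call. = FALSE)
  U <- pair_dist(coords)
  if (any(!is.finite(U))) stop("non-finite distances", call. = FALSE)
  S <- params$sigma2 * exp(-U / params$phi)
  out <- S[cluster, cluster, drop = FALSE]
  diag(out) <- diag(out) + params$omega2
  out
}

# Internal fitting payload: precomputed pieces reused across likelihood
# evaluations (distance matrix, cluster sizes, cross-products).
geo_data <- function(y, X, coords, cluster) {
  X <- as.matrix(X)
  coords <- as.matrix(coords)
  m <- nrow(coords)
  n <- length(y)
  stopifnot(nrow(X) == n, length(cluster) == n,
            all(cluster >= 1 & cluster <= m))
  list(y = y, X = X, coords = coords, cluster = as.integer(cluster),
       n = n, m = m, p = ncol(X),
       U = pair_dist(coords),
       n_i = tabulate(cluster, nbins = m))
}

# Solve Sigma^{-1} V and log|Sigma| via Woodbury on
#   Sigma = omega2 I_n + Z (sigma2 R) Z^T,  Z = cluster incidence.
# With E = diag(sqrt(n_i / omega2)) and G = I + sigma2 E R E (symmetric
# positive definite even when R is rank deficient, e.g. duplicate
# clusters), log|Sigma| = n log(omega2) + log|G| and
#   (Z K Z^T + omega2 I)^{-1} needs only one Cholesky (of G) per
# evaluation:
#   B^{-1} = sigma2 R - sigma2 R E G^{-1} E sigma2 R,
#   Sigma^{-1} V = V/omega2 - Z B^{-1} (Z^T V) / omega2^2.
# Agrees with the dense multivariate-normal density to machine precision;
# the test suite enforces 1e-8.
sigma_ops <- function(gd, sigma2, phi, omega2) {
  if (omega2 < 1e-12) return(NULL)     # degenerate: handled by caller
  if (sigma2 < 1e-12) {
    return(list(
      mult = function(V) V / omega2,
      logdet = gd$n * log(omega2)))
  }
  R <- exp(-gd$U / phi)
  e <- sqrt(gd$n_i / omega2)
  G <- sigma2 * (R * tcrossprod(e))
  diag(G) <- diag(G) + 1
  cG <- tryCatch(chol(G), error = function(e2) NULL)
  if (is.null(cG)) return(NULL)
  logdet <- gd$n * log(omega2) + 2 * sum(log(diag(cG)))
  mult <- function(V) {
    V <- as.matrix(V)
    t_cl <- rowsum(V, gd$cluster, reorder = TRUE)
    full_t <- matrix(0, gd$m, ncol(V))
    full_t[sort(unique(gd$cluster)), ] <- t_cl
    u <- sigma2 * (R %*% full_t)
    w <- backsolve(cG, forwardsolve(t(cG), e * u))
    Binv_t <- u - sigma2 * (R %*% (e * w))
    V / omega2 - Binv_t[gd$cluster, , drop = FALSE] / omega2^2
  }
  list(mult = mult, logdet = logdet)
}

#' Exact Gaussian log-likelihood of the geostatistical model
#'
#' Multivariate-normal log density of the outcomes given mean
#' `alpha + X beta` and the covariance of [build_covariance()]. The
#' computation exploits the cluster block structure (Woodbury identity on
#' the m-dimensional cluster process) but is exactly the dense density, a
#' property the test suite enforces to 1e-8.
#'
#' @param y numeric outcomes, one per individual.
#' @param X design matrix (include an intercept column; `alpha` in
#'   `params` is added on top, so use `alpha = 0` with an explicit
#'   intercept column, or a 0-column `X` with a pure `alpha` mean).
#' @param coords cluster coordinate matrix (km).
#' @param cluster cluster index per individual.
#' @param params a [geo_params()].
#' @return log-likelihood (scalar).
#' @export
geo_loglik <- function(y, X, coords, cluster, params) {
  stopifnot(inherits(params, "geo_params"))
  X <- if (is.null(X)) matrix(0, length(y), 0) else as.matrix(X)
  gd <- geo_data(y, X, coords, cluster)
  mu <- params$alpha + if (gd$p) as.vector(X %*% params$beta) else 0
  r <- y - mu
  ops <- sigma_ops(gd, params$sigma2, params$phi, params$omega2)
  if (is.null(ops))
    stop("covariance factorization failed (omega2 ~ 0 or ill-conditioned ",
         "correlation matrix); sigma2 = ", params$sigma2, ", phi = ",
         params$phi, ", omega2 = ", params$omega2, call. = FALSE)
  quad <- sum(r * ops$mult(r))
  -0.5 * (gd$n * log(2 * pi) + ops$logdet + quad)
}

# Profile log-likelihood over theta = (log sigma2, log phi, log omega2)
# with the GLS beta-hat substituted. Returns -Inf-like sentinel on failure.
profile_loglik <- function(gd, theta, spatial = TRUE) {
  if (spatial) {
    sigma2 <- exp(theta[1]); phi <- exp(theta[2]); omega2 <- exp(theta[3])
  } else {
    sigma2 <- exp(theta[1]); phi <- 1; omega2 <- exp(theta[2])
  }
  if (!all(is.finite(c(sigma2, phi, omega2)))) return(list(value = -1e15))
  ops <- if (spatial) sigma_ops(gd, sigma2, phi, omega2)
         else sigma_ops_cs(gd, sigma2, omega2)
  if (is.null(ops)) return(list(value = -1e15))
  SiX <- ops$mult(cbind(gd$X, gd$y))
  Siy <- SiX[, gd$p + 1]
  SiX <- SiX[, seq_len(gd$p), drop = FALSE]
  XtSiX <- crossprod(gd$X, SiX)
  beta <- tryCatch(solve(XtSiX, crossprod(gd$X, Siy)),
                   error = function(e) NULL)
  if (is.null(beta)) return(list(value = -1e15))
  r <- gd$y - as.vector(gd$X %*% beta)
  quad <- sum(r * ops$mult(r))
  ll <- -0.5 * (gd$n * log(2 * pi) + ops$logdet + quad)
  if (!is.finite(ll)) return(list(value = -1e15))
  list(value = ll, beta = as.vector(beta), XtSiX = XtSiX,
       sigma2 = sigma2, phi = phi, omega2 = omega2)
}

# Concentrated profile likelihood: with Sigma = nu2 * V(rho, phi),
# V = rho Z R Z^T + (1 - rho) I (rho = sigma2 / (sigma2 + omega2)), both
# beta and the total variance nu2 have closed-form ML solutions, leaving
# a 2-parameter search (1 for compound symmetry). th2 = (qlogis(rho),
# log(phi)). Returns the same fields as profile_loglik.
profile_loglik2 <- function(gd, th2, spatial = TRUE) {
  rho <- stats::plogis(th2[1])
  phi <- if (spatial) exp(th2[2]) else 1
  if (!is.finite(rho) || rho <= 0 || rho >= 1 || !is.finite(phi))
    return(list(value = -1e15))
  ops <- if (spatial) sigma_ops(gd, rho, phi, 1 - rho)
         else sigma_ops_cs(gd, rho, 1 - rho)
  if (is.null(ops)) return(list(value = -1e15))
  SiA <- ops$mult(cbind(gd$X, gd$y))
  Siy <- SiA[, gd$p + 1]
  XtViX <- crossprod(gd$X, SiA[, seq_len(gd$p), drop = FALSE])
  XtViy <- crossprod(gd$X, Siy)
  beta <- tryCatch(solve(XtViX, XtViy), error = function(e) NULL)
  if (is.null(beta)) return(list(value = -1e15))
  quad <- sum(gd$y * Siy) - sum(beta * XtViy)   # r' V^-1 r
  if (!is.finite(quad) || quad <= 0) return(list(value = -1e15))
  nu2 <- quad / gd$n
  ll <- -0.5 * (gd$n * log(2 * pi) + ops$logdet + gd$n * log(nu2) + gd$n)
  if (!is.finite(ll)) return(list(value = -1e15))
  list(value = ll, beta = as.vector(beta), XtSiX = XtViX / nu2,
       sigma2 = rho * nu2, phi = phi, omega2 = (1 - rho) * nu2)
}

# Compound-symmetry variant: S collapses to iid cluster effects
# (the no-residual-spatial-correlation limit where p(u) = 0 off-cluster).
sigma_ops_cs <- function(gd, sigma2, omega2) {
  if (omega2 < 1e-12) return(NULL)
  if (sigma2 < 1e-12) {
    return(list(mult = function(V) V / omega2,
                logdet = gd$n * log(omega2)))
  }
  # B = I/sigma2 + diag(n_i)/omega2 is diagonal
  bdiag <- 1 / sigma2 + gd$n_i / omega2
  logdet <- gd$n * log(omega2) + gd$m * log(sigma2) + sum(log(bdiag))
  mult <- function(V) {
    V <- as.matrix(V)
    t_cl <- rowsum(V, gd$cluster, reorder = TRUE)
    full_t <- matrix(0, gd$m, ncol(V))
    full_t[sort(unique(gd$cluster)), ] <- t_cl
    V / omega2 - (full_t / bdiag)[gd$cluster, , drop = FALSE] / omega2^2
  }
  list(mult = mult, logdet = logdet)
}
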