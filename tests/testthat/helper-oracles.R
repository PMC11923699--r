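# Independent oracles used across the suite. These deliberately avoid the
# package's blocked/efficient code paths: dense matrix algebra only.

# dense multivariate-normal log density of y ~ N(alpha + X beta, Sigma)
dense_mvn_loglik <- function(y, X, coords, cluster, params) {
  S <- geofalter::build_covariance(coords, cluster, params)
  mu <- params$alpha +
    if (length(params$beta)) as.vector(as.matrix(X) %*% params$beta) else 0
  r <- y - mu
  n <- length(y)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + as.numeric(t(r) %*% solve(S) %*% r))
}

# dense conditional-Gaussian (kriging) oracle: distribution of S at grid
# points given all individual observations, built from the full joint
# covariance of (S_grid, Y)
dense_krige_oracle <- function(fit, grid_xy) {
  p <- fit$params
  gd <- fit$gd
  grid_xy <- as.matrix(grid_xy)
  Dgo <- sqrt(outer(grid_xy[, 1], gd$coords[, 1], "-")^2 +
                outer(grid_xy[, 2], gd$coords[, 2], "-")^2)
  Dgg <- sqrt(outer(grid_xy[, 1], grid_xy[, 1], "-")^2 +
                outer(grid_xy[, 2], grid_xy[, 2], "-")^2)
  C_sy <- (p$sigma2 * exp(-Dgo / p$phi))[, gd$cluster, drop = FALSE]
  C_yy <- geofalter::build_covariance(gd$coords, gd$cluster, p)
  r <- gd$y - as.vector(gd$X %*% fit$coefficients)
  K <- C_sy %*% solve(C_yy)
  list(mean = as.vector(K %*% r),
       cov = p$sigma2 * exp(-Dgg / p$phi) - K %*% t(C_sy))
}

# tiny random fitting problem for oracle equivalence checks
random_instance <- function(seed, max_n = 50) {
  set.seed(seed)
  m <- sample(2:8, 1)
  n_i <- sample(1:6, m, replace = TRUE)
  while (sum(n_i) > max_n) n_i <- pmax(n_i - 1, 1)
  coords <- cbind(runif(m, 0, 100), runif(m, 0, 100))
  cluster <- rep(seq_len(m), times = n_i)
  n <- length(cluster)
  p <- sample(0:2, 1)
  X <- if (p) matrix(rnorm(n * p), n, p,
                     dimnames = list(NULL, paste0("v", 1:p)))
       else matrix(0, n, 0)
  params <- geofalter::geo_params(
    alpha = rnorm(1),
    beta = stats::setNames(rnorm(p), colnames(X)),
    sigma2 = runif(1, 0.05, 2),
    phi = runif(1, 2, 80),
    omega2 = runif(1, 0.1, 3))
  y <- rnorm(n, sd = 2)
  list(y = y, X = X, coords = coords, cluster = cluster, params = params)
}

# HAZ-like truth used by the recovery and prediction suites
haz_truth <- function(beta = c(spei_lag3 = 0.06)) {
  geofalter::geo_params(alpha = -1.23, beta = beta,
                        sigma2 = 0.15, phi = 18.28, omega2 = 2.02)
}

recovery_config <- function(seed, n_clusters = 300, ind = c(10, 10)) {
  geofalter::sim_config(
    n_clusters = n_clusters, ind_range = ind,
    true_params = haz_truth(),
    covariates = data.frame(name = "spei", kind = "monthly",
                            range_km = 80, sd = 1, seasonal_amp = 0),
    n_months = 36, seed = seed)
}
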