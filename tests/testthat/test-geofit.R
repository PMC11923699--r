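# one small shared survey keeps the fitting tests quick
small_survey <- local({
  cfg <- sim_config(n_clusters = 70, extent = c(0, 300, 0, 300),
                    ind_range = c(6, 12), n_months = 30,
                    true_params = geo_params(
                      alpha = -1.23, beta = c(spei_lag3 = 0.5),
                      sigma2 = 0.3, phi = 25, omega2 = 1.2),
                    covariates = data.frame(name = "spei",
                                            kind = "monthly",
                                            range_km = 80, sd = 1,
                                            seasonal_amp = 0),
                    seed = 77)
  simulate_survey(cfg)
})

test_that("geofit recovers a strong signal and satisfies AIC identity", {
  fit <- geofit(z ~ spei_lag3, data = small_survey$data, starts = 3,
                check_phi = FALSE)
  expect_s3_class(fit, "geofit")
  expect_true(fit$converged)
  # AIC = 2k - 2 logLik with k = 2 coefficients + 3 variance parameters
  expect_equal(fit$aic, 2 * 5 - 2 * fit$log_likelihood)
  expect_equal(fit$k, 5)
  expect_equal(AIC(fit), fit$aic)
  s <- summary(fit)
  expect_lt(s$coefficients["spei_lag3", "p"], 1e-6)
  # a strong beta = 0.5 signal is found with roughly the right size
  expect_gt(coef(fit)[["spei_lag3"]], 0.3)
  expect_lt(coef(fit)[["spei_lag3"]], 0.7)
  # reported maximum beats the truth's likelihood (it is the MLE)
  gd_truth <- small_survey$truth
  ll_truth <- geo_loglik(
    small_survey$data$z - 0,
    cbind(small_survey$data$spei_lag3),
    fit$gd$coords, fit$gd$cluster,
    geo_params(alpha = gd_truth$alpha, beta = c(x = 0.5),
               sigma2 = gd_truth$sigma2, phi = gd_truth$phi,
               omega2 = gd_truth$omega2))
  expect_gte(fit$log_likelihood, ll_truth - 1e-6)
  # CIs bracket the estimates
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= c(coef(fit), exp(fit$theta)) + 1e-10))
  expect_true(all(ci[, 2] >= c(coef(fit), exp(fit$theta)) - 1e-10))
})

test_that("a null model yields near-zero spatial variance and covered beta", {
  set.seed(55)
  loc <- data.frame(cluster_id = 1:120,
                    x_km = runif(120, 0, 400), y_km = runif(120, 0, 400))
  cl <- rep(1:120, each = 8)
  x <- rnorm(length(cl))
  dat <- data.frame(cluster_id = loc$cluster_id[cl],
                    x_km = loc$x_km[cl], y_km = loc$y_km[cl],
                    x = x, z = rnorm(length(cl), 0, 1.5))
  fit <- geofit(z ~ x, data = dat, starts = 3, check_phi = FALSE)
  s <- summary(fit)
  # beta truth 0 inside its CI, sigma2 near zero
  expect_gt(s$coefficients["x", "upper"], 0)
  expect_lt(s$coefficients["x", "lower"], 0)
  expect_lt(fit$params$sigma2, 0.15)
  expect_equal(fit$params$omega2 + fit$params$sigma2, 1.5^2,
               tolerance = 0.15)
})

test_that("the compound-symmetry variant drops phi and changes k", {
  fit_cs <- geofit(z ~ spei_lag3, data = small_survey$data,
                   correlation = "independent")
  expect_equal(fit_cs$k, 4)
  expect_equal(fit_cs$aic, 2 * 4 - 2 * fit_cs$log_likelihood)
  expect_equal(rownames(summary(fit_cs)$varcomp), c("sigma2", "omega2"))
  # on spatially structured data the spatial model should win the AIC
  fit_sp <- geofit(z ~ spei_lag3, data = small_survey$data, starts = 3,
                   check_phi = FALSE)
  expect_lt(fit_sp$aic, fit_cs$aic + 2)
})

test_that("phi flagged non-identifiable on spatially unstructured data", {
  set.seed(56)
  m <- 80
  loc <- data.frame(cluster_id = 1:m, x_km = runif(m, 0, 300),
                    y_km = runif(m, 0, 300))
  cl <- rep(1:m, each = 6)
  # no residual variation at the cluster level at all (within-cluster
  # centering removes it), so the spatial scale carries no information:
  # the WAZ-like situation in which the variance ratio collapses to the
  # boundary and the profile over phi is exactly flat
  z_raw <- rnorm(length(cl))
  dat <- data.frame(cluster_id = loc$cluster_id[cl],
                    x_km = loc$x_km[cl], y_km = loc$y_km[cl],
                    z = z_raw - ave(z_raw, cl))
  fit <- suppressWarnings(geofit(z ~ 1, data = dat, starts = 3,
                                 check_phi = TRUE))
  prof <- fit$phi_profile
  expect_s3_class(prof, "data.frame")
  expect_lt(diff(range(prof$loglik)), 0.05)
  expect_false(fit$phi_identifiable)
  # fallback was fitted and is the non-spatial variant
  expect_s3_class(fit$nonspatial, "geofit")
  expect_equal(fit$nonspatial$correlation, "independent")
  expect_lt(abs(fit$nonspatial$log_likelihood - fit$log_likelihood), 2)
})

test_that("missing covariate rows are excluded and counted", {
  dat <- small_survey$data
  dat$spei_lag3[c(3, 10)] <- NA
  expect_message(
    fit <- geofit(z ~ spei_lag3, data = dat, starts = 1,
                  check_phi = FALSE),
    "2 row")
  expect_equal(fit$n_dropped, 2)
  expect_equal(fit$n_individuals, nrow(dat) - 2)
})

test_that("lag scans rank lags by AIC with parsimony tie-breaks", {
  sv <- small_survey
  # scan over the single true lag returns it
  sc1 <- scan_lags(z ~ 1, sv$data, sv$monthly$spei, covariate = "spei",
                   lags = 3, starts = 2)
  expect_equal(nrow(sc1$table), 1)
  expect_equal(sc1$selected, 3)

  # the strong lag-3 signal is found against competitors
  sc <- scan_lags(z ~ 1, sv$data, sv$monthly$spei, covariate = "spei",
                  lags = c(1, 3, 6, 9), starts = 2)
  expect_equal(sc$selected, 3)
  expect_equal(sc$table$lag[which.min(sc$table$aic)], 3)
  expect_s3_class(sc$fit, "geofit")

  # a time-constant covariate gives identical AICs; shortest lag wins
  const <- matrix(rep(rnorm(sv$config$n_clusters), 30), ncol = 30)
  colnames(const) <- 1:30
  sc_const <- scan_lags(z ~ spei_lag3, sv$data, const,
                        covariate = "flat", lags = c(2, 5, 11),
                        starts = 1)
  expect_lt(diff(range(sc_const$table$aic)), 1e-4)
  expect_equal(sc_const$selected, 2)

  # a lag that cannot be constructed (birth too close to the series
  # start) is marked failed; the scan continues
  dat_early <- sv$data
  dat_early$birth_month[1] <- 8       # lag 12 would need month -4
  sc_fail <- scan_lags(z ~ 1, dat_early, sv$monthly$spei,
                       covariate = "spei", lags = c(3, 12), starts = 1)
  expect_true(sc_fail$table$failed[sc_fail$table$lag == 12])
  expect_false(sc_fail$table$failed[sc_fail$table$lag == 3])
  expect_equal(sc_fail$selected, 3)
  expect_equal(sc_fail$n_failed, 1)
})
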