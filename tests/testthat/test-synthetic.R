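test_that("sim_config validates the stated world", {
  expect_error(sim_config(n_clusters = 1), "n_clusters")
  expect_error(sim_config(extent = c(0, 0, 0, 100)), "positive area")
  expect_error(sim_config(n_months = 12), "n_months")
  expect_error(sim_config(covariates = data.frame(
    name = "a", kind = "monthly", range_km = -5, sd = 1)), "range_km")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("cluster locations are reproducible, in-domain and distinct", {
  cfg <- sim_config(n_clusters = 200, extent = c(0, 500, 0, 500),
                    seed = 99)
  a <- sim_cluster_locations(cfg)
  b <- sim_cluster_locations(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 200)
  expect_true(all(a$x_km >= 0 & a$x_km <= 500))
  expect_true(all(a$y_km >= 0 & a$y_km <= 500))
  expect_false(any(duplicated(a[, c("x_km", "y_km")])))
  c2 <- sim_cluster_locations(sim_config(n_clusters = 200, seed = 100))
  expect_false(identical(a$x_km, c2$x_km))
})

test_that("covariate stacks have the configured shape and seasonality", {
  cfg <- sim_config(n_clusters = 10, extent = c(0, 100, 0, 100),
                    cellsize = 20, n_months = 24,
                    covariates = data.frame(
                      name = c("arid", "rain"),
                      kind = c("constant", "monthly"),
                      range_km = c(50, 50), sd = c(1, 1),
                      seasonal_amp = c(0, 2)),
                    seed = 5)
  st <- sim_covariate_fields(cfg)
  expect_named(st$constant, "arid")
  expect_named(st$monthly, "rain")
  expect_length(st$monthly$rain, 24)
  expect_true(all(vapply(st$monthly$rain,
                         function(r) all(is.finite(r$values)),
                         logical(1))))
  # monthly spatial means track the 12-month sinusoid
  mns <- vapply(st$monthly$rain, function(r) mean(r$values), numeric(1))
  expect_gt(cor(mns, sin(2 * pi * (1:24) / 12)), 0.9)

  # seasonal amplitude 0: monthly means constant up to field noise
  cfg0 <- sim_config(n_clusters = 10, extent = c(0, 100, 0, 100),
                     cellsize = 20, n_months = 24,
                     covariates = data.frame(
                       name = "spei", kind = "monthly", range_km = 20,
                       sd = 1, seasonal_amp = 0),
                     seed = 6)
  st0 <- sim_covariate_fields(cfg0)
  mns0 <- vapply(st0$monthly$spei, function(r) mean(r$values), numeric(1))
  expect_lt(sd(mns0), 1)   # no seasonal swing beyond sampling noise
  expect_lt(abs(mean(mns0)), 0.75)
})

test_that("short-range fields decorrelate between neighboring cells", {
  # spatial range far below the cell size: neighbor correlation ~ 0;
  # empirical correlogram over replicate fields
  cc <- as.matrix(expand.grid(x = seq(5, 95, by = 10),
                              y = seq(5, 95, by = 10)))
  set.seed(8)
  f_short <- sim_monthly_at_points(cc, n_months = 60, range_km = 0.5)
  nbr <- which(abs(cc[, 1] - cc[1, 1]) == 10 & cc[, 2] == cc[1, 2])[1]
  r_short <- cor(f_short[1, ], f_short[nbr, ])
  expect_lt(abs(r_short), 0.2)
  # and a long-range field does correlate
  set.seed(8)
  f_long <- sim_monthly_at_points(cc, n_months = 60, range_km = 200)
  expect_gt(cor(f_long[1, ], f_long[nbr, ]), 0.7)
})

test_that("z-scores follow the exact generative model in its limits", {
  loc <- data.frame(cluster_id = 1:3,
                    x_km = c(0, 30, 70), y_km = c(0, 40, 10))
  cl <- rep(1:3, each = 4)
  X <- matrix(0, 12, 0)

  # degenerate limit: no spatial or nugget variance -> all equal alpha
  p0 <- geo_params(alpha = -1.23, sigma2 = 0, phi = 18.28, omega2 = 0)
  d0 <- simulate_zscores(loc, cl, X, p0, seed = 1)
  expect_equal(d0$z, rep(-1.23, 12))

  # omega2 = 0: individuals within a cluster share their S exactly
  p1 <- geo_params(alpha = 0, sigma2 = 0.5, phi = 20, omega2 = 0)
  d1 <- simulate_zscores(loc, cl, X, p1, seed = 2)
  expect_equal(as.numeric(tapply(d1$z, d1$cluster_id, function(v)
    max(v) - min(v))), rep(0, 3))

  # misalignment errors
  expect_error(simulate_zscores(loc, cl, matrix(0, 5, 0), p1), "align")
  expect_error(simulate_zscores(loc, c(cl[-1], 9), X, p1), "cluster")
})

test_that("simulated variance components match moment-based oracles", {
  # moment-matching at HAZ-like truth: var of cluster means ~ sigma2 +
  # omega2/m (short-range so clusters are near-independent), within-
  # cluster variance ~ omega2; averaged over 20 replicate seeds
  truth <- geo_params(alpha = -1.23, sigma2 = 0.15, phi = 18.28,
                      omega2 = 2.02)
  m_ind <- 10
  stats_rep <- vapply(1:20, function(s) {
    cfg <- sim_config(n_clusters = 300, ind_range = c(m_ind, m_ind),
                      true_params = truth,
                      covariates = data.frame(name = "spei",
                                              kind = "monthly",
                                              range_km = 80, sd = 1,
                                              seasonal_amp = 0),
                      seed = 1000 + s)
    loc <- sim_cluster_locations(cfg)
    cl <- rep(seq_len(300), each = m_ind)
    d <- simulate_zscores(loc, cl, matrix(0, 3000, 0), truth,
                          seed = 2000 + s)
    cm <- tapply(d$z, d$cluster_id, mean)
    within <- mean(tapply(d$z, d$cluster_id, var))
    c(var_cm = var(as.numeric(cm)), within = within)
  }, numeric(2))
  est_sigma2 <- mean(stats_rep["var_cm", ]) -
    mean(stats_rep["within", ]) / m_ind
  expect_equal(mean(stats_rep["within", ]), 2.02, tolerance = 0.03)
  expect_equal(est_sigma2, 0.15, tolerance = 0.35)  # MC error dominated
})

test_that("population rasters hit the requested total and are seeded", {
  cfg <- sim_config(n_clusters = 5, extent = c(0, 100, 0, 100),
                    cellsize = 10, seed = 4)
  u <- sim_population_raster(cfg, total = 7.2e6, mode = "uniform")
  expect_equal(sum(u$values), 7.2e6)
  expect_true(all(u$values >= 0))
  expect_equal(length(unique(as.vector(u$values))), 1)

  c1 <- sim_population_raster(cfg, total = 7.2e6, mode = "clustered")
  c2 <- sim_population_raster(cfg, total = 7.2e6, mode = "clustered")
  expect_identical(c1$values, c2$values)
  expect_equal(sum(c1$values), 7.2e6)
  expect_true(all(c1$values == floor(c1$values)))
})

test_that("the full survey generator is deterministic and self-consistent", {
  cfg <- sim_config(n_clusters = 40, extent = c(0, 200, 0, 200),
                    ind_range = c(5, 15), n_months = 24, seed = 12,
                    true_params = geo_params(
                      alpha = -1.23, beta = c(spei_lag3 = 0.06),
                      sigma2 = 0.15, phi = 18.28, omega2 = 2.02),
                    covariates = data.frame(name = "spei",
                                            kind = "monthly",
                                            range_km = 80, sd = 1,
                                            seasonal_amp = 0))
  a <- simulate_survey(cfg)
  b <- simulate_survey(cfg)
  expect_identical(a$data, b$data)
  expect_true(all(a$data$birth_month >= 13))
  expect_true(all(table(a$data$cluster_id) >= 5 &
                    table(a$data$cluster_id) <= 15))
  # standardized effect column
  expect_equal(mean(a$data$spei_lag3), 0, tolerance = 1e-10)
  expect_equal(sd(a$data$spei_lag3), 1, tolerance = 1e-10)
  # the lag-3 column is the stated calendar lookup
  cl_idx <- match(a$data$cluster_id, sort(unique(a$data$cluster_id)))
  raw <- a$monthly$spei[cbind(cl_idx, a$data$birth_month - 3)]
  expect_equal(a$data$spei_lag3, as.vector(scale(raw)))
})

test_that("simulated cluster means reproduce the theoretical variogram", {
  # generative fidelity: empirical variogram of cluster means vs
  # sigma2 (1 - exp(-u/phi)) + omega2/m, pooling replicates
  truth <- geo_params(alpha = 0, sigma2 = 1, phi = 30, omega2 = 1)
  m_ind <- 8
  set.seed(31)
  loc <- data.frame(cluster_id = 1:150,
                    x_km = runif(150, 0, 300), y_km = runif(150, 0, 300))
  cl <- rep(1:150, each = m_ind)
  gs <- replicate(15, {
    d <- simulate_zscores(loc, cl, matrix(0, length(cl), 0), truth)
    cm <- as.numeric(tapply(d$z, d$cluster_id, mean))
    vg <- empirical_variogram(cm, loc[, c("x_km", "y_km")], bins = 8,
                              max_dist = 150)
    vg$table$gamma
  })
  mid <- empirical_variogram(rnorm(150), loc[, c("x_km", "y_km")],
                             bins = 8, max_dist = 150)$table$mid
  theo <- truth$sigma2 * (1 - exp(-mid / truth$phi)) +
    truth$omega2 / m_ind
  expect_equal(rowMeans(gs), theo, tolerance = 0.12)
})
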