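# shared fitted model on a compact synthetic survey
pred_fit <- local({
  cfg <- sim_config(n_clusters = 60, extent = c(0, 200, 0, 200),
                    ind_range = c(8, 12), n_months = 24,
                    true_params = geo_params(
                      alpha = -1.23, beta = c(spei_lag3 = 0.06),
                      sigma2 = 0.15, phi = 18.28, omega2 = 2.02),
                    covariates = data.frame(name = "spei",
                                            kind = "monthly",
                                            range_km = 80, sd = 1,
                                            seasonal_amp = 0),
                    seed = 91)
  sv <- simulate_survey(cfg)
  list(sv = sv,
       fit = geofit(z ~ spei_lag3, data = sv$data, starts = 3,
                    check_phi = FALSE))
})

test_that("kriging matches the dense conditional-Gaussian oracle", {
  fit <- pred_fit$fit
  grid <- cbind(c(25, 60, 100, 150, 190, 5),
                c(25, 180, 100, 40, 190, 195))
  kr <- krige_latent(fit, grid, joint = TRUE)
  oracle <- dense_krige_oracle(fit, grid)
  expect_equal(kr$mean, oracle$mean, tolerance = 1e-8)
  expect_equal(kr$var, pmax(diag(oracle$cov), 0), tolerance = 1e-8)
  expect_equal(kr$cov, oracle$cov, tolerance = 1e-8)
  # kriging variance stays inside [0, sigma2]
  expect_true(all(kr$var >= 0 & kr$var <= fit$params$sigma2 + 1e-12))
})

test_that("kriging limits: exact interpolation and prior reversion", {
  # omega2 -> 0: prediction at a data cluster reproduces its residual
  sv <- pred_fit$sv
  loc <- sv$locations
  set.seed(71)
  cl <- rep(1:60, each = 5)
  d0 <- simulate_zscores(loc, cl, matrix(0, length(cl), 0),
                         geo_params(alpha = 0, sigma2 = 0.5, phi = 30,
                                    omega2 = 0))
  d0$z <- d0$z + rnorm(length(cl), sd = 1e-4)  # tiny nugget for stability
  fit0 <- geofit(z ~ 1, data = d0, starts = 2, check_phi = FALSE)
  kr0 <- krige_latent(fit0, as.matrix(loc[1:5, c("x_km", "y_km")]))
  rbar <- tapply(d0$z - coef(fit0)[1], d0$cluster_id, mean)
  expect_equal(kr0$mean, as.numeric(rbar[1:5]), tolerance = 1e-3)
  expect_true(all(kr0$var < 1e-3))

  # far beyond the practical range: mean -> 0, variance -> sigma2
  fit <- pred_fit$fit
  far <- cbind(5000, 5000)
  krf <- krige_latent(fit, far)
  expect_equal(krf$mean, 0, tolerance = 1e-8)
  expect_equal(krf$var, fit$params$sigma2, tolerance = 1e-8)
})

test_that("prevalence surfaces follow the normal-CDF law", {
  fit <- pred_fit$fit
  # symmetry anchor: when the predictive mean equals the threshold the
  # prevalence is exactly one half
  p <- stats::pnorm((-2 - (-2)) / sqrt(0.3 + fit$params$omega2))
  expect_equal(p, 0.5)

  # population-mean anchor: mean -1.23, total SD 1.48, no spatial term
  prev <- stats::pnorm((-2 + 1.23) / 1.48)
  expect_equal(prev, 0.301, tolerance = 0.002)

  # predict() agrees with the hand-applied closed form cell by cell
  gridpts <- expand.grid(x_km = seq(20, 180, length.out = 5),
                         y_km = seq(20, 180, length.out = 5))
  gridpts$spei_lag3 <- 0
  surf <- predict(fit, gridpts, type = "prevalence", method = "closed")
  kr <- krige_latent(fit, as.matrix(gridpts[, 1:2]))
  mu <- coef(fit)[1] +
    coef(fit)[2] * (0 - fit$std_record$center) / fit$std_record$scale +
    kr$mean
  expect_equal(surf$prevalence,
               as.numeric(pnorm((-2 - mu) /
                                  sqrt(kr$var + fit$params$omega2))),
               tolerance = 1e-10)
  expect_true(all(surf$prevalence >= 0 & surf$prevalence <= 1))

  # prevalence is monotone decreasing in the predictive mean at fixed
  # variance: one location, increasing covariate values
  same_loc <- data.frame(x_km = 100, y_km = 100,
                         spei_lag3 = seq(-2, 2, length.out = 7))
  sm <- predict(fit, same_loc, type = "prevalence", method = "closed")
  expect_equal(sd(sm$sd), 0)
  if (coef(fit)[["spei_lag3"]] > 0) {
    expect_true(all(diff(sm$prevalence) < 0))
  } else {
    expect_true(all(diff(sm$prevalence) > 0))
  }
})

test_that("closed-form and simulated prevalence agree cellwise", {
  fit <- pred_fit$fit
  gridpts <- expand.grid(x_km = seq(30, 170, length.out = 5),
                         y_km = seq(30, 170, length.out = 5))
  gridpts$spei_lag3 <- 0.2
  closed <- predict(fit, gridpts, type = "prevalence", method = "closed")
  sim <- predict(fit, gridpts, type = "prevalence",
                 method = "simulation", n_sims = 10000, seed = 123)
  # Monte Carlo SE of the averaged-CDF estimator, cellwise
  expect_true(all(abs(closed$prevalence - sim$prevalence) < 0.01))
  mc_se <- apply(cbind(closed$prevalence), 1, function(p)
    sqrt(p * (1 - p) / 10000))
  expect_true(all(abs(closed$prevalence - sim$prevalence) <=
                    pmax(3 * mc_se, 0.005)))
  expect_error(predict(fit, gridpts, type = "prevalence",
                       method = "simulation", n_sims = 100), "500")
})

test_that("masked cells propagate and are reported", {
  fit <- pred_fit$fit
  gridpts <- data.frame(x_km = c(10, 20, 30), y_km = c(10, 20, 30),
                        spei_lag3 = c(0, NA, 1))
  surf <- predict(fit, gridpts, type = "prevalence")
  expect_true(is.na(surf$prevalence[2]))
  expect_equal(attr(surf, "n_masked"), 1)
})

test_that("case counts multiply prevalence and population exactly", {
  set.seed(17)
  prev <- geo_raster(matrix(runif(24), 4, 6), cellsize = 5)
  pop <- geo_raster(matrix(rpois(24, 500), 4, 6), cellsize = 5)
  cases <- counts_surface(prev, pop)
  expect_equal(cases$values, prev$values * pop$values)
  expect_true(all(cases$values <= pop$values))
  zero <- prev; zero$values[] <- 0
  expect_true(all(counts_surface(zero, pop)$values == 0))
  bad <- geo_raster(matrix(1, 4, 6), cellsize = 7)
  expect_error(counts_surface(prev, bad), "geometr")
  expect_equal(counts_surface(c(0.1, 0.5), c(100, 10)), c(10, 5))
})

test_that("district aggregation conserves cases under any partition", {
  # 2 x 2 grid with hand-set prevalence and population
  surf <- data.frame(x = c(0.5, 1.5, 0.5, 1.5),
                     y = c(1.5, 1.5, 0.5, 0.5),
                     prevalence = c(0.2, 0.4, 0.1, 0.3))
  pop <- c(100, 200, 300, 400)
  west <- rbind(c(0, 0), c(1, 0), c(1, 2), c(0, 2))
  east <- rbind(c(1, 0), c(2, 0), c(2, 2), c(1, 2))
  polys <- geo_polygons(list(west = west, east = east))
  ds <- aggregate_polygons(surf, polys, pop)
  # west: cells (0.5,1.5) and (0.5,0.5): cases 20 + 30 = 50, pop 400
  expect_equal(ds$cases[ds$district == "west"], 0.2 * 100 + 0.1 * 300)
  expect_equal(ds$population[ds$district == "west"], 400)
  expect_equal(ds$prevalence[ds$district == "west"], 50 / 400)
  # east: cases 80 + 120 = 200, pop 600
  expect_equal(ds$cases[ds$district == "east"], 200)
  expect_equal(ds$prevalence[ds$district == "east"], 200 / 600)
  # conservation across the partition
  expect_equal(sum(ds$cases), sum(surf$prevalence * pop))
  expect_equal(attr(ds, "n_unassigned"), 0)

  # one all-covering polygon equals the population-weighted mean
  all_p <- geo_polygons(list(domain = rbind(c(0, 0), c(2, 0), c(2, 2),
                                            c(0, 2))))
  ds_all <- aggregate_polygons(surf, all_p, pop)
  expect_equal(ds_all$prevalence,
               sum(surf$prevalence * pop) / sum(pop))

  # partial coverage: unassigned cells are reported, cases conserved
  only_west <- geo_polygons(list(west = west))
  ds_w <- aggregate_polygons(surf, only_west, pop)
  expect_equal(attr(ds_w, "n_unassigned"), 2)
  expect_equal(ds_w$cases + attr(ds_w, "unassigned_cases"),
               sum(surf$prevalence * pop))

  # zero-population polygon flagged with undefined prevalence
  surf0 <- surf; pop0 <- c(0, 0, 300, 400)
  north <- rbind(c(0, 1), c(2, 1), c(2, 2), c(0, 2))
  south <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  expect_warning(
    ds0 <- aggregate_polygons(surf0, geo_polygons(list(n = north,
                                                       s = south)),
                              pop0),
    "zero population")
  expect_true(is.na(ds0$prevalence[ds0$district == "n"]))
})

test_that("random partitions of a simulated surface conserve cases", {
  set.seed(19)
  cc <- expand.grid(x = seq(2.5, 97.5, by = 5), y = seq(2.5, 97.5, by = 5))
  surf <- data.frame(x = cc$x, y = cc$y, prevalence = runif(400))
  pop <- rpois(400, 50)
  total <- sum(surf$prevalence * pop)
  for (split in c(20, 50, 80)) {
    left <- rbind(c(0, 0), c(split, 0), c(split, 100), c(0, 100))
    right <- rbind(c(split, 0), c(100, 0), c(100, 100), c(split, 100))
    ds <- aggregate_polygons(surf, geo_polygons(list(l = left, r = right)),
                             pop)
    expect_equal(sum(ds$cases), total)
    expect_equal(sum(ds$population), sum(pop))
  }
})
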