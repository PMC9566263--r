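make_station_fixture <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    x = runif(n, 0, 20000), y = runif(n, 0, 20000),
    pm25 = runif(n, 40, 100),
    aod = runif(n), pop = runif(n), ndvi = runif(n),
    road = runif(n), np_dist = runif(n))
}

test_that("constant response yields a constant intercept and zero slopes", {
  st <- make_station_fixture(12)
  st$pm25 <- 77
  fit <- fit_gwr(st, bandwidth = 3000)
  expect_equal(unname(fit$coefficients[, 1]), rep(77, 12), tolerance = 1e-6)
  expect_equal(max(abs(fit$coefficients[, -1])), 0, tolerance = 1e-6)
})

test_that("huge bandwidth reduces GWR to global OLS", {
  st <- make_station_fixture(10)
  fit <- fit_gwr(st, bandwidth = 1e12)
  X <- cbind(1, as.matrix(st[, c("aod", "pop", "ndvi", "road", "np_dist")]))
  beta_ols <- solve(t(X) %*% X, t(X) %*% st$pm25)
  for (i in seq_len(nrow(st))) {
    expect_equal(unname(fit$coefficients[i, ]), drop(beta_ols),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("noise-free global linear data are fit exactly at any bandwidth", {
  # bandwidths wide enough that every local kernel sees a full-rank design
  st <- make_station_fixture(30)
  beta <- c(50, 20, -3, 8, 1.5, -0.5)
  X <- cbind(1, as.matrix(st[, c("aod", "pop", "ndvi", "road", "np_dist")]))
  st$pm25 <- drop(X %*% beta)
  for (bw in c(6000, 20000)) {
    fit <- fit_gwr(st, bandwidth = bw)
    expect_equal(unname(t(fit$coefficients)), matrix(beta, 6, 30),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
})

test_that("fitted plus residual reproduces the observations", {
  st <- make_station_fixture(12, seed = 3)
  fit <- fit_gwr(st, bandwidth = "cv")
  expect_equal(fit$fitted + fit$residuals, st$pm25)
  expect_lte(fit$r2, 1)
})

test_that("input contracts are enforced", {
  st <- make_station_fixture(10)
  expect_error(fit_gwr(st[1:5, ]), "at least 7 stations")
  st2 <- st
  st2$x[2] <- st2$x[1]; st2$y[2] <- st2$y[1]
  expect_error(fit_gwr(st2, bandwidth = 1000), "duplicate")
  expect_error(fit_gwr(st[, -5], bandwidth = 1000), "lacks columns")
  expect_error(fit_gwr(st, bandwidth = -1), "positive")
})

test_that("grid prediction interpolates coefficients and clamps", {
  st <- make_station_fixture(10, seed = 5)
  fit <- fit_gwr(st, bandwidth = 1e12)

  # all-zero covariates: prediction equals the (interpolated) intercept
  g0 <- data.frame(x = c(1000, 9000), y = c(2000, 11000),
                   aod = 0, pop = 0, ndvi = 0, road = 0, np_dist = 0)
  p0 <- predict_grid(fit, g0)
  expect_equal(p0$value, rep(unname(fit$coefficients[1, 1]), 2),
               tolerance = 1e-8)
  expect_identical(attr(p0, "provenance"), "gwr_predicted")

  # colocated cell with an exact global fit reproduces the observation
  stx <- st
  beta <- c(60, 10, 2, -5, 1, -0.2)
  X <- cbind(1, as.matrix(st[, c("aod", "pop", "ndvi", "road", "np_dist")]))
  stx$pm25 <- drop(X %*% beta)
  fitx <- fit_gwr(stx, bandwidth = 1e12)
  gx <- data.frame(x = st$x[3], y = st$y[3], aod = st$aod[3], pop = st$pop[3],
                   ndvi = st$ndvi[3], road = st$road[3], np_dist = st$np_dist[3])
  expect_equal(predict_grid(fitx, gx)$value, stx$pm25[3], tolerance = 1e-6)

  expect_error(predict_grid(fit, g0[, -3]), "lacks covariate")
})

test_that("hand-set coefficients produce dot-product predictions", {
  fit <- structure(list(
    coefficients = matrix(c(10, 2, 0, 0, 0, 0), 1, 6,
                          dimnames = list(NULL, c("(Intercept)", "aod", "pop",
                                                  "ndvi", "road", "np_dist"))),
    coords = cbind(x = 0, y = 0),
    covariates = c("aod", "pop", "ndvi", "road", "np_dist")),
    class = "gwr_fit")
  g <- data.frame(x = c(1, 2, 3), y = 0, aod = c(0, 1, 2), pop = 0, ndvi = 0,
                  road = 0, np_dist = 0)
  expect_equal(predict_grid(fit, g)$value, c(10, 12, 14))
})

test_that("local coefficients recover smooth truth on a dense station net", {
  city <- generate_city(tiny_config(seed = 21, n_stations = 40, noise_sd = 0.5))
  fit <- fit_gwr(stations_at_hour(city, 9), bandwidth = "cv")
  b1 <- city$truth$beta$aod[city$truth$station_cells]
  rmse <- sqrt(mean((fit$coefficients[, "aod"] - b1)^2))
  amp <- city$config$beta_fields$aod$amp
  expect_lt(rmse, 0.5 * amp)
  expect_gt(fit$r2, 0.6)
})
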