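test_that("constant data give a pure-nugget model and constant predictions", {
  set.seed(1)
  x <- runif(20, 0, 1e4); y <- runif(20, 0, 1e4)
  vg <- fit_variogram(x, y, rep(5, 20))
  expect_true(vg$pure_nugget)
  expect_equal(vg$sill, 0)
  kr <- krige(x, y, rep(5, 20), vg, c(100, 5000), c(100, 5000),
              return_weights = TRUE)
  expect_equal(kr$value, c(5, 5))
  expect_equal(colSums(attr(kr, "weights")), c(1, 1))
})

test_that("variogram recovers the generating range within a factor of two", {
  set.seed(42)
  n <- 400
  x <- runif(n, 0, 10000); y <- runif(n, 0, 10000)
  true_range <- 1500; true_sill <- 10
  D <- as.matrix(dist(cbind(x, y)))
  C <- true_sill * exp(-D / true_range)
  z <- drop(chol(C + diag(1e-8, n)) %*% rnorm(n))
  vg <- fit_variogram(x, y, z, model = "exponential")
  expect_gt(vg$range_m, true_range / 2)
  expect_lt(vg$range_m, true_range * 2)
  expect_gte(vg$sill, vg$nugget)
})

test_that("empty-lag and short inputs error", {
  set.seed(2)
  x <- runif(12, 0, 1000); y <- runif(12, 0, 1000)
  z <- rnorm(12)
  expect_error(empirical_variogram(x, y, z, max_lag = 1e-6), "minimum pair")
  expect_error(empirical_variogram(x[1:5], y[1:5], z[1:5]), "at least 10")
})

test_that("zero-nugget kriging is exact at the data points", {
  set.seed(7)
  n <- 25
  x <- runif(n, 0, 5000); y <- runif(n, 0, 5000)
  z <- 50 + 10 * sin(x / 1000) + rnorm(n)
  vg <- variogram_model("exponential", nugget = 0, psill = 8, range_m = 1200)
  kr <- krige(x, y, z, vg, x, y)
  expect_equal(kr$value, z, tolerance = 1e-8)
})

test_that("two-point kriging matches the hand-solved system", {
  vg <- variogram_model("exponential", nugget = 0.5, psill = 4, range_m = 1000)
  x <- c(0, 2000); y <- c(0, 0); z <- c(10, 20)
  tx <- 500; ty <- 0
  # independent oracle: assemble and solve the 3x3 system directly
  gam <- function(h) ifelse(h <= 0, 0, 0.5 + 4 * (1 - exp(-h / 1000)))
  A <- rbind(c(gam(0), gam(2000), 1),
             c(gam(2000), gam(0), 1),
             c(1, 1, 0))
  b <- c(gam(500), gam(1500), 1)
  w <- solve(A, b)
  kr <- krige(x, y, z, vg, tx, ty, return_weights = TRUE)
  expect_equal(drop(attr(kr, "weights")), w[1:2], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(kr$value, sum(w[1:2] * z), tolerance = 1e-10)
  expect_equal(sum(attr(kr, "weights")), 1, tolerance = 1e-12)
})

test_that("duplicate data points are collapsed to their mean", {
  vg <- variogram_model("exponential", nugget = 0, psill = 2, range_m = 500)
  expect_message(
    kr <- krige(c(0, 0, 1000), c(0, 0, 0), c(10, 14, 20), vg, 0, 0),
    "duplicate")
  expect_equal(kr$value, 12, tolerance = 1e-8)
})

test_that("block averaging is an area-weighted mean with convex bounds", {
  # uniform surface
  expect_equal(unname(block_average(rep(3, 6), c(1, 1, 2, 2, 3, 3))),
               rep(3, 3))
  # two equal-area cells at 10 and 20 average to 15
  expect_equal(unname(block_average(c(10, 20), c(1, 1))), 15)
  # area weighting
  expect_equal(unname(block_average(c(10, 20), c(1, 1),
                                    cell_areas = c(3, 1))), 12.5)
  # convexity on a random fixture, including the matrix form
  set.seed(3)
  vals <- matrix(runif(40, 0, 100), 20, 2)
  units <- sample(1:4, 20, replace = TRUE)
  bm <- block_average(vals, units)
  expect_true(all(bm >= min(vals) & bm <= max(vals)))
  # empty unit: error without coordinates, nearest-cell fallback with them
  expect_error(block_average(c(1, 2), c(1, 1), unit_ids = c(1, 2)),
               "no member cell")
  expect_message(
    fb <- block_average(c(1, 2), c(1, 1), unit_ids = c(1, 2),
                        cell_xy = cbind(c(0, 10), 0), unit_xy = cbind(c(0, 9), 0)),
    "fallback")
  expect_equal(unname(fb[2]), 2)
})

test_that("surface estimation keeps kriging consistent with the fishnet", {
  city <- get_tiny_city()
  s_raw <- estimate_surfaces(city, hours = 9, krige_surface = FALSE)
  s_kr <- estimate_surfaces(city, hours = 9, krige_surface = TRUE)
  expect_true(all(s_kr$conc >= 0))
  # kriging the fishnet back onto itself stays close to the GWR prediction
  expect_lt(mean(abs(s_kr$conc - s_raw$conc)) / mean(s_raw$conc), 0.15)
  expect_gt(s_raw$r2[1], 0.6)
})
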