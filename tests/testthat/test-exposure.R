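test_that("exposure intensity is the thresholded hourly sum", {
  r <- exposure_intensity(c(50, 100), c(10, 20))
  expect_equal(r$E, 2500)
  expect_equal(r$NT, 2)
  r75 <- exposure_intensity(c(50, 100), c(10, 20), threshold = 75)
  expect_equal(r75$E, 2000)
  expect_equal(r75$NT, 1)
  r0 <- exposure_intensity(c(50, 100), c(0, 0))
  expect_equal(r0$E, 0)
  expect_equal(r0$NT, 2)
  expect_error(exposure_intensity(c(1, 2), c(1, -1)), "negative")
  expect_error(exposure_intensity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("exposure intensity is linear in population density", {
  set.seed(9)
  for (i in 1:5) {
    conc <- runif(24, 20, 120)
    dens <- runif(24, 0, 5000)
    e1 <- exposure_intensity(conc, dens)$E
    e2 <- exposure_intensity(conc, 2 * dens)$E
    expect_equal(e2, 2 * e1, tolerance = 1e-12)
  }
  m <- exposure_intensity_blocks(matrix(c(50, 100), 1), matrix(c(10, 20), 1))
  expect_equal(m$E, 2500)
})

worker_day_fixture <- function(home_conc = 80, work_conc = 100) {
  # single weekday, one worker group commuting from community 1 to 2
  conc <- rbind(rep(home_conc, 24), rep(work_conc, 24))
  rownames(conc) <- c("1", "2")
  od <- data.frame(home_id = 1, work_id = 2, group = "worker_19_59",
                   count = 100)
  list(conc = conc, od = od)
}

test_that("weighted concentration reproduces the worker-day hand sum", {
  f <- worker_day_fixture()
  pod <- weighted_concentration(f$od, f$conc)
  # 14 home hours at 80 and 10 work hours at 100 average to 88.33
  expect_equal(pod$pod[pod$community_id == "1"], (80 * 14 + 100 * 10) / 24,
               tolerance = 1e-12)
  expect_equal(round(pod$pod[pod$community_id == "1"], 2), 88.33)
})

test_that("uniform concentration makes pod schedule-invariant", {
  set.seed(4)
  conc <- matrix(64.5, 3, 48, dimnames = list(c("1", "2", "3"), NULL))
  od <- data.frame(home_id = c(1, 1, 2, 3), work_id = c(2, 1, 3, 3),
                   group = c("worker_19_59", "elderly_65p", "worker_19_59",
                             "child_0_6"),
                   count = c(10, 20, 30, 40))
  pod <- weighted_concentration(od, conc)
  expect_equal(pod$pod, rep(64.5, 3), tolerance = 1e-12)
})

test_that("home-bound groups experience the residence mean", {
  set.seed(5)
  conc <- matrix(runif(48, 40, 120), 2, 24, dimnames = list(c("1", "2"), NULL))
  od <- data.frame(home_id = 1, work_id = 1, group = "elderly_65p", count = 10)
  pod <- weighted_concentration(od, conc)
  expect_equal(pod$pod[1], mean(conc["1", ]))
  # bounds: pod lies within the experienced hourly range
  expect_gte(pod$pod[1], min(conc["1", ]))
  expect_lte(pod$pod[1], max(conc["1", ]))
})

test_that("pod stays within experienced concentration bounds on the city", {
  city <- get_tiny_city()
  conc <- block_average(city$truth$pm25, city$grid$community_id)
  pod <- weighted_concentration(city$od_groups, conc)
  expect_true(all(pod$pod >= min(conc) - 1e-9 & pod$pod <= max(conc) + 1e-9))
})

test_that("zero-population communities are flagged and excluded", {
  conc <- matrix(50, 2, 24, dimnames = list(c("1", "2"), NULL))
  od <- data.frame(home_id = 1, work_id = 1, group = "elderly_65p", count = 5)
  expect_message(pod <- weighted_concentration(od, conc), "zero population")
  expect_true(is.na(pod$pod[pod$community_id == "2"]))
  expect_identical(attr(pod, "excluded"), "2")
})

test_that("out-of-region workplaces fall back to home concentration", {
  conc <- matrix(c(rep(60, 24), rep(90, 24)), 2, 24, byrow = TRUE,
                 dimnames = list(c("1", "2"), NULL))
  od <- data.frame(home_id = 1, work_id = 99, group = "worker_19_59",
                   count = 10)
  expect_message(pod <- weighted_concentration(od, conc), "outside the region")
  expect_equal(pod$pod[1], 60)
})

test_that("dynamic equals static without commuting, exceeds it with inflow", {
  # no commuting: every group home-bound
  conc <- matrix(runif(72, 40, 100), 3, 24, dimnames = list(as.character(1:3), NULL))
  od0 <- data.frame(home_id = 1:3, work_id = 1:3, group = "elderly_65p",
                    count = c(10, 20, 30))
  pod0 <- weighted_concentration(od0, conc)
  stat <- static_exposure(conc)
  expect_equal(pod0$pod, stat$static_mean, tolerance = 1e-12)
  m0 <- exposure_means(pod0, stat)
  expect_equal(m0$dynamic, m0$static, tolerance = 1e-12)

  # commuting into a +10 ug/m3 centre raises the dynamic mean
  conc2 <- conc
  conc2["1", ] <- conc2["1", ] + 10
  odc <- rbind(od0, data.frame(home_id = c(2, 3), work_id = 1,
                               group = "worker_19_59", count = c(50, 50)))
  podc <- weighted_concentration(odc, conc2)
  mc <- exposure_means(podc, static_exposure(conc2))
  expect_gt(mc$dynamic, mc$static)
})

test_that("single-community city is flow-invariant", {
  conc <- matrix(runif(24, 50, 80), 1, 24, dimnames = list("1", NULL))
  od <- data.frame(home_id = 1, work_id = 1,
                   group = c("worker_19_59", "elderly_65p"), count = c(5, 5))
  pod <- weighted_concentration(od, conc)
  expect_equal(pod$pod, mean(conc))
})

test_that("decile profile sorts, splits evenly and weights by population", {
  # constant pod: all deciles equal
  d <- decile_exposure(rep(7, 20), runif(20), rep(1, 20))
  expect_equal(d$mean_pod, rep(7, 10))
  expect_equal(d$n, rep(2L, 10))

  # pod strictly increasing with the proportion: decile means increase
  prop <- seq(0.01, 0.3, length.out = 30)
  pod <- 80 + 20 * prop + 0.001 * seq_len(30)
  d2 <- decile_exposure(pod, prop)
  expect_true(all(diff(d2$mean_pod) > 0))

  # remainder spread to the lowest deciles
  d3 <- decile_exposure(seq_len(13), seq_len(13))
  expect_equal(d3$n, c(2L, 2L, 2L, rep(1L, 7)))

  expect_error(decile_exposure(1:5, 1:5), "at least 10")
})
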