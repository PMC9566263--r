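full_facility_set <- function(dist = 100) {
  cats <- names(default_facility_weights())
  data.frame(x = dist, y = 0, category = cats)
}

test_that("a full facility set within 500 m scores the 16-point ceiling", {
  expect_equal(base_index(c(0, 0), full_facility_set(100)), 16)
  expect_equal(sum(default_facility_weights()), 16)
})

test_that("distance bands attenuate facility weights", {
  # single grocery at 700 m: weight 3 attenuated by 25%
  f <- data.frame(x = 700, y = 0, category = "grocery")
  expect_equal(base_index(c(0, 0), f), 3 * 0.75)
  # boundary 500 m falls in the 25% band (half-open bands)
  expect_equal(base_index(c(0, 0), data.frame(x = 500, y = 0,
                                              category = "grocery")), 2.25)
  # 1000-1500 m band: 88% attenuation
  expect_equal(base_index(c(0, 0), data.frame(x = 1200, y = 0,
                                              category = "grocery")),
               3 * 0.12)
  # nothing within 1500 m scores zero
  expect_equal(base_index(c(0, 0), full_facility_set(2000)), 0)
  expect_error(base_index(c(0, 0), data.frame(x = 1, y = 1, category = "gym")),
               "unknown facility category")
})

test_that("only the nearest facility per category contributes", {
  f <- data.frame(x = c(100, 400, 2000), y = 0,
                  category = c("park", "park", "grocery"))
  expect_equal(base_index(c(0, 0), f), 1)
})

test_that("base index is monotone in facility proximity and addition", {
  set.seed(6)
  for (i in 1:10) {
    n <- 8
    f <- data.frame(x = runif(n, -2000, 2000), y = runif(n, -2000, 2000),
                    category = sample(names(default_facility_weights()), n,
                                      replace = TRUE))
    b0 <- base_index(c(0, 0), f)
    # moving one facility closer never decreases the index
    f2 <- f
    f2$x[1] <- f2$x[1] / 2; f2$y[1] <- f2$y[1] / 2
    expect_gte(base_index(c(0, 0), f2), b0 - 1e-12)
    # adding a facility never decreases it
    f3 <- rbind(f, data.frame(x = 100, y = 100, category = "bank"))
    expect_gte(base_index(c(0, 0), f3), b0 - 1e-12)
    expect_true(b0 >= 0 && b0 <= 16)
  }
})

test_that("street form decays the point index by at most 10%", {
  expect_equal(point_index(16, 220, 30), 14.4)
  expect_equal(point_index(16, 100, 250), 16)
  expect_equal(point_index(0, 220, 30), 0)
  # interior bands
  expect_equal(point_index(10, 150, 100), 10 * (1 - 0.02 - 0.03))
  expect_error(point_index(10, -5, 100), "non-negative")
  expect_error(point_index(-1, 100, 100), "non-negative")
  # ratio invariant over a random sweep
  set.seed(8)
  bl <- runif(50, 0, 400); idd <- runif(50, 0, 400)
  p <- point_index(rep(16, 50), bl, idd)
  expect_true(all(p / 16 >= 0.90 - 1e-12 & p / 16 <= 1 + 1e-12))
})

test_that("area index is a population-weighted mean", {
  expect_equal(area_index(c(10, 20), c(5, 5)), 15)
  expect_equal(area_index(c(10, 20), c(1, 0)), 10)
  expect_equal(area_index(c(7, 7, 7), c(1, 2, 3)), 7)
  expect_message(v <- area_index(c(10, 20), c(0, 0)), "zero population")
  expect_equal(v, 15)
  expect_error(area_index(numeric(0), numeric(0)), "no cells")
})

test_that("decay tables round-trip through YAML unchanged", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  tabs <- list(weights = as.list(default_facility_weights()),
               decay = distance_decay_policy(),
               street = street_form_decay())
  yaml::write_yaml(tabs, tmp)
  back <- yaml::read_yaml(tmp)
  expect_equal(unlist(back$weights), default_facility_weights())
  expect_equal(as.data.frame(back$decay), distance_decay_policy())
  expect_equal(as.data.frame(back$street$block_length),
               street_form_decay()$block_length)
})

test_that("city walkscore is centre-high and within range", {
  city <- get_tiny_city()
  ws <- walkscore_city(city)
  expect_true(all(ws$cells$base_index >= 0 & ws$cells$base_index <= 16))
  expect_true(all(ws$cells$point_index <= ws$cells$base_index + 1e-12))
  expect_true(all(ws$units$area_index >= 0 & ws$units$area_index <= 16))
  # centre cells walk better than corner cells
  g <- city$grid
  cx <- city$config$extent_km * 500
  r <- sqrt((g$x - cx)^2 + (g$y - cx)^2)
  expect_gt(mean(ws$cells$base_index[r < quantile(r, 0.25)]),
            mean(ws$cells$base_index[r > quantile(r, 0.75)]))
})
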