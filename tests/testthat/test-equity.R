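test_that("Lorenz/Gini handles equality and extreme concentration", {
  lz <- lorenz_gini(rep(5, 10), runif(10, 1, 100))
  expect_equal(lz$gini, 0, tolerance = 1e-12)
  expect_equal(lz$x[1], 0)
  expect_equal(utils::tail(lz$y, 1), 1)

  # all burden on one unit holding 1/N of the population
  N <- 10
  lz2 <- lorenz_gini(c(rep(0, N - 1), 100), rep(1, N))
  expect_equal(lz2$gini, (N - 1) / N, tolerance = 1e-12)

  # all-zero exposure degenerates to equality
  expect_equal(lorenz_gini(rep(0, 5), rep(1, 5))$gini, 0)
  expect_error(lorenz_gini(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(lorenz_gini(c(1, 2), c(0, 0)), "positive")
})

test_that("trapezoid Gini equals the pairwise-difference oracle", {
  set.seed(14)
  pod <- runif(50, 40, 120)
  popn <- sample(50:5000, 50)
  lz <- lorenz_gini(pod, popn)
  expect_equal(lz$gini, gini_pairwise(pod, popn), tolerance = 1e-9)
  # scale invariance and curve convexity
  expect_equal(lorenz_gini(3.7 * pod, popn)$gini, lz$gini, tolerance = 1e-12)
  expect_true(all(diff(diff(lz$y) / diff(lz$x)) > -1e-9))
  expect_true(lz$gini >= 0 && lz$gini <= 1)
})

test_that("the top-share reading view inverts the curve", {
  lz <- lorenz_gini(c(rep(1, 6), rep(10, 4)), rep(1, 10))
  # top 40% of the population holds the four high-exposure units
  expect_equal(lorenz_top_share(lz, 0.4), 40 / 46, tolerance = 1e-9)
})

test_that("contiguity weights follow queen and rook definitions", {
  q <- lattice_weights(3, "queen")
  r <- lattice_weights(3, "rook")
  centre <- 5  # (row 2, col 2) of the 3x3 lattice
  expect_equal(length(q$nb[[centre]]), 8)
  expect_equal(length(r$nb[[centre]]), 4)
  expect_equal(length(q$nb[[1]]), 3)
  expect_equal(length(r$nb[[1]]), 2)
  # symmetry and row standardisation
  for (i in seq_along(q$nb)) {
    expect_equal(sum(q$w[[i]]), 1)
    for (j in q$nb[[i]]) expect_true(i %in% q$nb[[j]])
  }
})

test_that("knn weights are symmetrised by union", {
  set.seed(15)
  pts <- data.frame(unit_id = 1:12, x = runif(12), y = runif(12))
  w <- build_weights(pts, scheme = "knn", k = 3)
  for (i in seq_along(w$nb)) {
    expect_gte(length(w$nb[[i]]), 3)
    for (j in w$nb[[i]]) expect_true(i %in% w$nb[[j]])
  }
})

test_that("checkerboard with rook weights gives Moran's I of -1", {
  w <- lattice_weights(4, "rook")
  m <- expand.grid(col = 1:4, row = 1:4)
  z <- as.numeric((m$row + m$col) %% 2 == 0)
  bm <- bivariate_moran(z, z, w, n_perm = 99, seed = 1, local_inference = FALSE)
  expect_equal(bm$I, -1, tolerance = 1e-12)
})

test_that("global I equals the mean of the local statistics", {
  set.seed(16)
  w <- lattice_weights(5, "queen")
  x <- rnorm(25); y <- rnorm(25)
  bm <- bivariate_moran(x, y, w, n_perm = 99, seed = 2)
  expect_equal(bm$I, mean(bm$local$local_i), tolerance = 1e-12)
  # reproducible under a fixed seed
  bm2 <- bivariate_moran(x, y, w, n_perm = 99, seed = 2)
  expect_identical(bm$p_value, bm2$p_value)
  expect_identical(bm$local$pseudo_p, bm2$local$pseudo_p)
  expect_true(bm$p_value > 0 && bm$p_value <= 1)
})

test_that("degenerate inputs are rejected", {
  w <- lattice_weights(4, "rook")
  expect_error(bivariate_moran(rep(1, 16), rnorm(16), w, seed = 1),
               "constant variable")
  expect_error(bivariate_moran(rnorm(16), rnorm(16), w), "seed")
  empty <- structure(list(ids = 1:3, nb = rep(list(integer(0)), 3),
                          w = rep(list(numeric(0)), 3)),
                     class = "spatial_weights")
  expect_error(bivariate_moran(rnorm(3), rnorm(3), empty, seed = 1),
               "degenerate weights")
})

test_that("LISA labels a planted high-high patch and partitions all units", {
  w <- lattice_weights(6, "queen")
  m <- expand.grid(col = 1:6, row = 1:6)
  patch <- m$row <= 2 & m$col <= 2
  set.seed(17)
  x <- ifelse(patch, 10, 0) + rnorm(36, 0, 0.1)
  y <- ifelse(patch, 8, 0) + rnorm(36, 0, 0.1)
  bm <- bivariate_moran(x, y, w, n_perm = 499, seed = 3)
  cl <- lisa_clusters(bm, alpha = 0.05)
  inner <- which(m$row == 1 & m$col == 1)
  expect_equal(as.character(cl$cluster[inner]), "HH")
  expect_true(all(levels(cl$cluster) == c("HH", "HL", "LH", "LL", "ns")))
  expect_equal(sum(attr(cl, "counts")), 36)
  # alpha = 0 silences everything
  cl0 <- lisa_clusters(bm, alpha = 0)
  expect_true(all(cl0$cluster == "ns"))
})

test_that("permutation p-values are calibrated under independence", {
  # modest replicate count for the routine suite; the acceptance test
  # re-runs this at 500 replicates
  w <- lattice_weights(7, "rook")
  set.seed(18)
  rej <- mean(replicate(60, {
    x <- rnorm(49); y <- rnorm(49)
    bivariate_moran(x, y, w, n_perm = 199, seed = sample.int(1e6, 1),
                    local_inference = FALSE)$p_value <= 0.05
  }))
  expect_lt(rej, 0.15)
})
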