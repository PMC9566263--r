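# Shared fixtures: a small city reused across test files (generated once),
# and independent oracles for Jenks and Gini.

tiny_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(extent_km = 8, grid_res_m = 1000, n_blocks = 16, n_communities = 6,
         n_stations = 8, n_hours = 48, total_population = 5e4, seed = seed),
    list(...))
  do.call(city_config, args)
}

.fixtures <- new.env()

get_tiny_city <- function() {
  if (is.null(.fixtures$city)) .fixtures$city <- generate_city(tiny_config())
  .fixtures$city
}

# exhaustive Jenks oracle: tries every composition of n into k contiguous
# classes over the sorted values
jenks_oracle_wss <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(seg) sum((seg - mean(seg))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1, simplify = FALSE)
  if (k == 1) splits <- list(integer(0))
  for (sp in splits) {
    edges <- c(0, sp, n)
    tot <- 0
    for (c in seq_len(k)) tot <- tot + ssd(v[(edges[c] + 1):edges[c + 1]])
    if (tot < best) best <- tot
  }
  best
}

# pairwise mean-absolute-difference Gini for population-weighted data
gini_pairwise <- function(exposure, population) {
  p <- population / sum(population)
  mu <- sum(p * exposure)
  sum(outer(p, p) * abs(outer(exposure, exposure, `-`))) / (2 * mu)
}

# rook-contiguity weights on an n x n lattice of singleton units
lattice_weights <- function(n, scheme = "rook") {
  m <- expand.grid(col = seq_len(n), row = seq_len(n))
  build_weights(data.frame(unit_id = seq_len(n * n), row = m$row, col = m$col),
                scheme = scheme)
}
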