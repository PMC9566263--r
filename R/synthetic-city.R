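#' Generate a synthetic study region
#'
#' Builds a complete synthetic monocentric city with the statistical structure
#' the downstream analysis assumes: a fishnet covariate grid, blocks and
#' communities tiling the region, monitoring stations observing a latent
#' spatially-varying-coefficient PM2.5 surface, commuting origin-destination
#' groups that redistribute the working-age population on weekday working
#' hours, centre-weighted service facilities, and age-composition gradients
#' (elderly proportions highest centrally, child proportions highest at the
#' periphery). The latent surface and the true local coefficient fields are
#' returned in `$truth` for recovery testing.
#'
#' Each covariate field is a monocentric radial trend plus its own smooth
#' pseudo-random plane-wave component, so covariates decorrelate locally and
#' the local coefficients are identifiable from station data.
#'
#' @param config A [city_config()].
#' @return An object of class `synthetic_city`: a list with elements `config`,
#'   `grid` (fishnet cells with static covariates, street-form metrics and
#'   block/community membership), `blocks`, `communities`, `od_groups`,
#'   `facilities`, `stations` (long station-hour table), `covariates`
#'   (hourly AOD and population-density matrices), `population` (hourly
#'   community counts and densities) and `truth`.
#' @export
generate_city <- function(config) {
  if (!inherits(config, "city_config")) stop("config must be a city_config")
  extent_m <- config$extent_km * 1000
  res <- config$grid_res_m
  nx <- as.integer(round(extent_m / res))
  H <- config$n_hours
  cell_area_km2 <- (res / 1000)^2

  ## --- fishnet and static covariate fields -------------------------------
  set.seed(derive_seed(config$seed, 1L))
  grid <- expand.grid(col = seq_len(nx), row = seq_len(nx))
  grid <- grid[, c("row", "col")]
  grid$cell_id <- seq_len(nrow(grid))
  grid$x <- (grid$col - 0.5) * res
  grid$y <- (grid$row - 0.5) * res
  cx <- extent_m / 2
  r <- sqrt((grid$x - cx)^2 + (grid$y - cx)^2)
  rmax <- sqrt(2) * extent_m / 2

  g_aod <- plane_wave_field(grid$x, grid$y, extent_m)
  g_ndvi <- plane_wave_field(grid$x, grid$y, extent_m)
  g_road <- plane_wave_field(grid$x, grid$y, extent_m)
  g_resid <- plane_wave_field(grid$x, grid$y, extent_m)

  # cell-scale texture: 1 km heterogeneity of the satellite- and map-derived
  # covariates, without which all fields are locally linear in (x, y) and the
  # local coefficients are not identifiable from station data
  n_cells <- nrow(grid)
  t_aod <- stats::rnorm(n_cells)
  t_ndvi <- stats::rnorm(n_cells)
  t_road <- stats::rnorm(n_cells)

  aod_base <- 0.7 + 0.4 * exp(-(r / (0.35 * extent_m))^2) + 0.3 * g_aod +
    0.3 * t_aod
  aod_base <- pmax(aod_base, 0.05)
  ndvi <- pmin(pmax(0.25 + 0.35 * (r / rmax) + 0.2 * g_ndvi + 0.08 * t_ndvi,
                    -1), 1)
  road <- pmax(3500 * exp(-(r / (0.4 * extent_m))^2) + 1500 + 1200 * g_road +
                 800 * t_road, 0)
  # single major industrial source in the north-west quadrant
  src <- c(0.2, 0.75) * extent_m
  np_dist <- sqrt((grid$x - src[1])^2 + (grid$y - src[2])^2)

  # street form: short blocks and dense intersections centrally
  block_length_m <- 100 + 130 * (r / rmax) +
    10 * plane_wave_field(grid$x, grid$y, extent_m)
  int_density_sqmi <- pmax(30 + 250 * exp(-(r / (0.45 * extent_m))^2) +
                             15 * plane_wave_field(grid$x, grid$y, extent_m), 1)

  # true coefficient surfaces (time-invariant)
  bf <- config$beta_fields
  # coefficient surfaces vary at supra-regional wavelengths so they are
  # smooth at any plausible kernel scale
  beta <- lapply(bf, function(b) {
    b$mean + b$amp * plane_wave_field(grid$x, grid$y, extent_m,
                                      n_waves = 2, wavelength_frac = c(4, 2.5))
  })
  day_phase <- stats::runif(1, 0, 2 * pi)
  diurnal_phase <- stats::runif(1, 0, 2 * pi)

  grid$aod_base <- aod_base
  grid$ndvi <- ndvi
  grid$road <- road
  grid$np_dist <- np_dist
  grid$block_length_m <- block_length_m
  grid$int_density_sqmi <- int_density_sqmi
  grid$area_km2 <- cell_area_km2

  ## --- blocks and communities -------------------------------------------
  set.seed(derive_seed(config$seed, 2L))
  if (config$n_blocks == nrow(grid)) {
    grid$block_id <- grid$cell_id
  } else {
    km <- suppressWarnings(stats::kmeans(cbind(grid$x, grid$y), config$n_blocks,
                                         iter.max = 100, nstart = 3))
    grid$block_id <- km$cluster
  }
  blocks <- data.frame(block_id = sort(unique(grid$block_id)))
  blocks$x <- as.numeric(tapply(grid$x, grid$block_id, mean)[as.character(blocks$block_id)])
  blocks$y <- as.numeric(tapply(grid$y, grid$block_id, mean)[as.character(blocks$block_id)])
  blocks$n_cells <- as.integer(table(grid$block_id)[as.character(blocks$block_id)])
  blocks$area_km2 <- blocks$n_cells * cell_area_km2
  if (config$n_communities == nrow(blocks)) {
    blocks$community_id <- blocks$block_id
  } else {
    km2 <- suppressWarnings(stats::kmeans(cbind(blocks$x, blocks$y),
                                          config$n_communities,
                                          iter.max = 100, nstart = 3))
    blocks$community_id <- km2$cluster
  }
  grid$community_id <- blocks$community_id[match(grid$block_id, blocks$block_id)]

  communities <- data.frame(community_id = sort(unique(blocks$community_id)))
  cid <- as.character(communities$community_id)
  csum <- function(v) as.numeric(tapply(v, blocks$community_id, sum)[cid])
  communities$x <- csum(blocks$x * blocks$n_cells) / csum(blocks$n_cells)
  communities$y <- csum(blocks$y * blocks$n_cells) / csum(blocks$n_cells)
  communities$area_km2 <- csum(blocks$area_km2)

  ## --- population, age composition, OD flows ----------------------------
  set.seed(derive_seed(config$seed, 3L))
  rc <- sqrt((communities$x - cx)^2 + (communities$y - cx)^2)
  res_weight <- (exp(-(rc / (0.45 * extent_m))^2) + 0.08) * communities$area_km2
  communities$pop <- apportion(config$total_population, res_weight)

  ag <- config$age_gradients
  rn <- rc / rmax
  communities$prop_65p <- ag$elderly_center + (ag$elderly_edge - ag$elderly_center) * rn
  communities$prop_0_6 <- ag$child_center + (ag$child_edge - ag$child_center) * rn
  communities$prop_19_59 <- rep(ag$worker, nrow(communities))

  communities$n_elderly <- as.integer(round(communities$prop_65p * communities$pop))
  communities$n_children <- as.integer(round(communities$prop_0_6 * communities$pop))
  communities$n_workers <- as.integer(round(communities$prop_19_59 * communities$pop))
  communities$n_other <- communities$pop - communities$n_elderly -
    communities$n_children - communities$n_workers

  # employment attractiveness: central communities draw commuters
  attract <- exp(-(rc / (0.30 * extent_m))^2) + 0.05
  od_list <- vector("list", nrow(communities))
  for (i in seq_len(nrow(communities))) {
    w_i <- communities$n_workers[i]
    commuters <- as.integer(round(config$commute_fraction * w_i))
    stay <- w_i - commuters
    dest_counts <- if (commuters > 0) {
      as.integer(stats::rmultinom(1, commuters, attract))
    } else {
      integer(nrow(communities))
    }
    dest_counts[i] <- dest_counts[i] + stay
    keep <- which(dest_counts > 0)
    home <- communities$community_id[i]
    rows <- data.frame(
      home_id = home,
      work_id = communities$community_id[keep],
      group = "worker_19_59",
      count = dest_counts[keep])
    extra <- data.frame(
      home_id = home, work_id = home,
      group = c("elderly_65p", "child_0_6", "other"),
      count = c(communities$n_elderly[i], communities$n_children[i],
                communities$n_other[i]))
    od_list[[i]] <- rbind(rows, extra[extra$count > 0, ])
  }
  od_groups <- do.call(rbind, od_list)
  rownames(od_groups) <- NULL

  ## --- hourly population fields -----------------------------------------
  ids <- communities$community_id
  workers_od <- od_groups[od_groups$group == "worker_19_59" &
                            od_groups$home_id != od_groups$work_id, ]
  outflow <- tapply(workers_od$count, factor(workers_od$home_id, levels = ids), sum)
  inflow <- tapply(workers_od$count, factor(workers_od$work_id, levels = ids), sum)
  outflow[is.na(outflow)] <- 0
  inflow[is.na(inflow)] <- 0
  at_work <- is_work_hour(0:(H - 1L))
  pop_counts <- matrix(rep(communities$pop, H), ncol = H,
                       dimnames = list(ids, NULL))
  shift <- as.numeric(inflow - outflow)
  pop_counts[, at_work] <- pop_counts[, at_work] + shift
  if (config$jitter_population) {
    jit <- matrix(stats::rpois(length(pop_counts), lambda = 25) - 25,
                  nrow = nrow(pop_counts))
    pop_counts <- pmax(pop_counts + jit, 0)
  }
  pop_density <- pop_counts / communities$area_km2

  ## --- hourly covariates and latent surface ------------------------------
  days <- day_of_week(0:(H - 1L))
  day_mult <- 1 + 0.10 * sin(2 * pi * (0:6) / 7 + day_phase)
  aod_hour <- outer(aod_base, day_mult[days + 1L])
  comm_idx <- match(grid$community_id, ids)
  pop_hour <- pop_density[comm_idx, , drop = FALSE]
  rownames(pop_hour) <- NULL

  hod <- hour_of_day(0:(H - 1L))
  diurnal <- 5 * sin(2 * pi * (hod - 9) / 24 + diurnal_phase) +
    2 * sin(2 * pi * days / 7)
  pm25_truth <- beta$intercept + beta$aod * aod_hour + beta$pop * pop_hour +
    beta$ndvi * ndvi + beta$road * road + beta$np * np_dist + 2 * g_resid
  pm25_truth <- sweep(pm25_truth, 2, diurnal, `+`)
  pm25_truth <- pmax(pm25_truth, 1)

  ## --- facilities ---------------------------------------------------------
  set.seed(derive_seed(config$seed, 4L))
  categories <- names(default_facility_weights())
  n_per_cat <- max(8L, as.integer(round(nrow(communities) / 3)))
  fac_n <- n_per_cat * length(categories)
  fr <- pmin(abs(stats::rexp(fac_n, rate = 1 / (0.25 * extent_m))), 0.68 * extent_m)
  fth <- stats::runif(fac_n, 0, 2 * pi)
  facilities <- data.frame(
    x = pmin(pmax(cx + fr * cos(fth), 0), extent_m),
    y = pmin(pmax(cx + fr * sin(fth), 0), extent_m),
    category = rep(categories, each = n_per_cat))

  ## --- stations -----------------------------------------------------------
  set.seed(derive_seed(config$seed, 5L))
  st_cells <- sample(grid$cell_id, config$n_stations)
  st_truth <- pm25_truth[st_cells, , drop = FALSE]
  noise <- matrix(stats::rnorm(length(st_truth), 0, config$noise_sd),
                  nrow = nrow(st_truth))
  st_obs <- st_truth + noise
  stations <- data.frame(
    station_id = rep(seq_len(config$n_stations), times = H),
    x = rep(grid$x[st_cells], times = H),
    y = rep(grid$y[st_cells], times = H),
    hour = rep(0:(H - 1L), each = config$n_stations),
    pm25 = pmax(as.vector(st_obs), 0),
    aod = as.vector(aod_hour[st_cells, , drop = FALSE]),
    pop = as.vector(pop_hour[st_cells, , drop = FALSE]),
    ndvi = rep(ndvi[st_cells], times = H),
    road = rep(road[st_cells], times = H),
    np_dist = rep(np_dist[st_cells], times = H))

  structure(list(
    config = config,
    grid = grid,
    blocks = blocks,
    communities = communities,
    od_groups = od_groups,
    facilities = facilities,
    stations = stations,
    covariates = list(aod = aod_hour, pop = pop_hour),
    population = list(counts = pop_counts, density = pop_density),
    truth = list(pm25 = pm25_truth, beta = beta, station_cells = st_cells,
                 station_pm25 = st_truth)
  ), class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf(
    "synthetic_city: %d cells, %d blocks, %d communities, %d stations, %d hours\n",
    nrow(x$grid), nrow(x$blocks), nrow(x$communities),
    x$config$n_stations, x$config$n_hours))
  invisible(x)
}

#' Hourly population snapshot
#'
#' Per-community population density at one hour of the simulated week, the
#' synthetic stand-in for hourly location-based-service (LBS) population
#' counts.
#'
#' @param city A [generate_city()] result.
#' @param hour 0-based hour index in `0:(n_hours - 1)`.
#' @return Data frame with `community_id`, `count` (persons) and `density`
#'   (person/km2).
#' @export
population_snapshot <- function(city, hour) {
  stopifnot(inherits(city, "synthetic_city"))
  H <- city$config$n_hours
  if (length(hour) != 1L || !is.finite(hour) || hour < 0 || hour >= H) {
    stop(sprintf("hour must lie in 0..%d", H - 1L), call. = FALSE)
  }
  h <- as.integer(hour) + 1L
  data.frame(community_id = city$communities$community_id,
             count = city$population$counts[, h],
             density = city$population$density[, h],
             row.names = NULL)
}

#' Station records for a single hour
#'
#' @param city A [generate_city()] result.
#' @param hour 0-based hour index.
#' @return One-hour slice of the long station table.
#' @export
stations_at_hour <- function(city, hour) {
  stopifnot(inherits(city, "synthetic_city"))
  out <- city$stations[city$stations$hour == hour, , drop = FALSE]
  if (nrow(out) == 0L) stop("hour out of range", call. = FALSE)
  rownames(out) <- NULL
  out
}
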