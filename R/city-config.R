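#' Configuration for the synthetic study region
#'
#' Defines a square monocentric city tiled by a fishnet grid. Blocks are
#' aggregations of fishnet cells, communities aggregations of blocks, mirroring
#' the two analysis units of the exposure pipeline. Station observations of
#' PM2.5 are generated from a latent spatially-varying-coefficient model over
#' five covariates (AOD, population density, NDVI, road density, distance to
#' industry) plus Gaussian noise, and hourly population redistribution follows
#' commuting origin-destination flows.
#'
#' @param extent_km Side length of the square region, km.
#' @param grid_res_m Fishnet cell size, m; must divide the extent.
#' @param n_blocks Number of urban blocks (cell aggregations).
#' @param n_communities Number of communities (block aggregations).
#' @param n_stations Number of monitoring stations (at least 6).
#' @param n_hours Simulated hours, divisible by 24 (default one week = 168).
#' @param seed Integer RNG seed; a fixed seed reproduces the city exactly.
#' @param total_population Residents in the region.
#' @param noise_sd Station observation noise, ug/m3.
#' @param commute_fraction Share of workers whose workplace is drawn from the
#'   employment-attractiveness distribution rather than fixed at home.
#' @param beta_fields Per-covariate spatially varying coefficient surfaces:
#'   a named list (`intercept`, `aod`, `pop`, `ndvi`, `road`, `np`) of
#'   `list(mean =, amp =)` giving the field mean and plane-wave amplitude.
#' @param age_gradients Centre/edge proportions controlling the
#'   elderly-central / children-peripheral composition gradients.
#' @param jitter_population If TRUE, add Poisson jitter to hourly community
#'   counts (off by default: redistribution is deterministic and
#'   schedule-driven).
#' @return An object of class `city_config`.
#' @export
city_config <- function(extent_km = 20, grid_res_m = 1000, n_blocks = 120,
                        n_communities = 40, n_stations = 10, n_hours = 168L,
                        seed = 1L, total_population = 4e5, noise_sd = 2,
                        commute_fraction = 0.6,
                        beta_fields = default_beta_fields(),
                        age_gradients = list(elderly_center = 0.25,
                                             elderly_edge = 0.10,
                                             child_center = 0.04,
                                             child_edge = 0.12,
                                             worker = 0.55),
                        jitter_population = FALSE) {
  stop_if_not_scalar_number(extent_km, "extent_km")
  stop_if_not_scalar_number(grid_res_m, "grid_res_m")
  if (extent_km <= 0 || grid_res_m <= 0) {
    stop("region extent and grid resolution must be positive", call. = FALSE)
  }
  extent_m <- extent_km * 1000
  if (abs(extent_m / grid_res_m - round(extent_m / grid_res_m)) > 1e-9) {
    stop("grid_res_m must divide the region extent", call. = FALSE)
  }
  n_cells <- as.integer(round(extent_m / grid_res_m))^2
  if (n_stations < 6) stop("need at least 6 monitoring stations", call. = FALSE)
  if (n_stations > n_cells) stop("more stations than fishnet cells", call. = FALSE)
  if (n_hours <= 0 || n_hours %% 24 != 0) {
    stop("n_hours must be a positive multiple of 24", call. = FALSE)
  }
  if (n_blocks < n_communities || n_blocks > n_cells) {
    stop("need n_communities <= n_blocks <= number of cells", call. = FALSE)
  }
  if (commute_fraction < 0 || commute_fraction > 1) {
    stop("commute_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  needed <- c("intercept", "aod", "pop", "ndvi", "road", "np")
  if (!all(needed %in% names(beta_fields))) {
    stop("beta_fields must name: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  for (nm in needed) {
    bf <- beta_fields[[nm]]
    if (!is.finite(bf$mean) || !is.finite(bf$amp)) {
      stop("beta field means and amplitudes must be finite", call. = FALSE)
    }
  }
  structure(list(
    extent_km = extent_km, grid_res_m = grid_res_m, n_blocks = as.integer(n_blocks),
    n_communities = as.integer(n_communities), n_stations = as.integer(n_stations),
    n_hours = as.integer(n_hours), seed = as.integer(seed),
    total_population = total_population, noise_sd = noise_sd,
    commute_fraction = commute_fraction, beta_fields = beta_fields,
    age_gradients = age_gradients, jitter_population = isTRUE(jitter_population)
  ), class = "city_config")
}

#' Default spatially varying coefficient surfaces
#'
#' Means and plane-wave amplitudes for the local regression coefficients of the
#' latent PM2.5 model. Units follow the covariates: the AOD slope is ug/m3 per
#' unit AOD, the population slope ug/m3 per person/km2, the NDVI slope ug/m3
#' per NDVI unit, the road slope ug/m3 per m/km2 of road density, and the
#' industry slope ug/m3 per metre of distance to the industrial source.
#' Magnitudes are chosen so each term contributes a few to a few tens of ug/m3
#' and the latent surface stays in a realistic urban range (roughly 40-100
#' ug/m3).
#'
#' @return Named list of `list(mean, amp)` per coefficient surface.
#' @export
default_beta_fields <- function() {
  list(
    intercept = list(mean = 55,      amp = 8),
    aod       = list(mean = 25,      amp = 8),
    pop       = list(mean = 2e-3,    amp = 6e-4),
    ndvi      = list(mean = -12,     amp = 4),
    road      = list(mean = 1.2e-3,  amp = 4e-4),
    np        = list(mean = -5e-4,   amp = 1.5e-4)
  )
}

#' @export
print.city_config <- function(x, ...) {
  cat(sprintf(
    "city_config: %g km x %g km, %g m fishnet, %d blocks / %d communities\n",
    x$extent_km, x$extent_km, x$grid_res_m, x$n_blocks, x$n_communities))
  cat(sprintf("  %d stations, %d hours, population %g, seed %d\n",
              x$n_stations, x$n_hours, x$total_population, x$seed))
  invisible(x)
}
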