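#' Facility category weights
#'
#' Importance/substitutability weights for the ten service-facility
#' categories; the weights sum to 16, the ceiling of the walkability index.
#'
#' @return Named numeric vector of weights.
#' @export
default_facility_weights <- function() {
  c(grocery = 3, mall = 2, restaurants = 3, cafe = 2, bookstore = 1,
    park = 1, entertainment = 1, hospital = 1, school = 1, bank = 1)
}

#' Distance-decay policy for facility access
#'
#' Half-open distance bands `[lo, hi)` and the attenuation applied to a
#' facility's weight: no attenuation within 500 m, 25% between 500 and
#' 1000 m, 88% between 1000 and 1500 m, full attenuation beyond 1500 m.
#'
#' @return Data frame `lo`, `hi` (m), `decay` (fraction in [0, 1]).
#' @export
distance_decay_policy <- function() {
  data.frame(lo = c(0, 500, 1000, 1500),
             hi = c(500, 1000, 1500, Inf),
             decay = c(0, 0.25, 0.88, 1))
}

#' Street-form decay tables
#'
#' Five-level attenuation by mean block length and by intersection density
#' (per square mile); each table decays at most 5%, the combined decay at
#' most 10%. Bands are half-open `[lo, hi)`.
#'
#' @return List of two data frames, `block_length` and `int_density`, each
#'   with `lo`, `hi`, `decay` (fraction).
#' @export
street_form_decay <- function() {
  list(
    block_length = data.frame(
      lo = c(0, 120, 150, 165, 180, 195),
      hi = c(120, 150, 165, 180, 195, Inf),
      decay = c(0, 1, 2, 3, 4, 5) / 100),
    int_density = data.frame(
      lo = c(0, 60, 90, 120, 150, 200),
      hi = c(60, 90, 120, 150, 200, Inf),
      decay = c(5, 4, 3, 2, 1, 0) / 100)
  )
}

#' Convert intersection density from per km2 to per square mile
#'
#' @param x Intersections per km2.
#' @return Intersections per square mile.
#' @export
per_km2_to_per_sqmi <- function(x) x * 2.58999

validate_decay_policy <- function(policy) {
  errs <- character(0)
  if (any(policy$lo[-1] != policy$hi[-nrow(policy)])) {
    errs <- c(errs, "distance-decay bands are not contiguous")
  }
  if (is.unsorted(policy$decay)) {
    errs <- c(errs, "distance-decay must be non-decreasing with distance")
  }
  if (any(policy$decay < 0 | policy$decay > 1)) {
    errs <- c(errs, "decay fractions must lie in [0, 1]")
  }
  errs
}

#' Basic walkability index of an origin point
#'
#' Sums, over facility categories, the category weight attenuated by the
#' distance band of the nearest facility of that category. Categories with no
#' facility inside the outermost finite band contribute nothing. Only the
#' nearest facility per category contributes, keeping the fixed ceiling of 16.
#'
#' @param origin Length-2 numeric `c(x, y)` in metres.
#' @param facilities Data frame `x`, `y`, `category`.
#' @param weights Named weight vector, see [default_facility_weights()].
#' @param decay A [distance_decay_policy()] table.
#' @return Basic walkability index in `[0, sum(weights)]`.
#' @export
base_index <- function(origin, facilities,
                       weights = default_facility_weights(),
                       decay = distance_decay_policy()) {
  errs <- validate_decay_policy(decay)
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  unknown <- setdiff(unique(facilities$category), names(weights))
  if (length(unknown)) {
    stop("unknown facility category: ", paste(unknown, collapse = ", "),
         "; known: ", paste(names(weights), collapse = ", "), call. = FALSE)
  }
  total <- 0
  for (cat in names(weights)) {
    fc <- facilities[facilities$category == cat, , drop = FALSE]
    if (nrow(fc) == 0L) next
    d <- min(sqrt((fc$x - origin[1])^2 + (fc$y - origin[2])^2))
    total <- total + weights[[cat]] * (1 - band_value(d, decay$lo, decay$decay))
  }
  total
}

#' Single-point walkability index
#'
#' Attenuates a basic index by street form: the block-length band decay plus
#' the intersection-density band decay (at most 10% combined).
#'
#' @param base Basic walkability index (>= 0).
#' @param block_length_m Mean block length within the cell, m.
#' @param int_density_sqmi Intersection density, per square mile.
#' @param decay A [street_form_decay()] table pair.
#' @return Single-point index, `base * (1 - total decay)`.
#' @export
point_index <- function(base, block_length_m, int_density_sqmi,
                        decay = street_form_decay()) {
  if (any(base < 0)) stop("base index must be non-negative", call. = FALSE)
  if (any(block_length_m < 0) || any(int_density_sqmi < 0)) {
    stop("street-form metrics must be non-negative", call. = FALSE)
  }
  d_bl <- band_value(block_length_m, decay$block_length$lo,
                     decay$block_length$decay)
  d_id <- band_value(int_density_sqmi, decay$int_density$lo,
                     decay$int_density$decay)
  base * (1 - (d_bl + d_id))
}

#' Area walkability index of a spatial unit
#'
#' Population-weighted mean of the single-point indices of the unit's grid
#' cells; the weight of a cell is its share of the unit's population. With no
#' population in the unit the unweighted mean is used, with a message.
#'
#' @param point_indices Single-point indices of the unit's cells.
#' @param populations Cell populations (same order).
#' @return Area walkability index.
#' @export
area_index <- function(point_indices, populations) {
  if (length(point_indices) == 0L) stop("unit has no cells", call. = FALSE)
  if (length(point_indices) != length(populations)) {
    stop("index/population length mismatch", call. = FALSE)
  }
  if (any(populations < 0)) stop("negative cell population", call. = FALSE)
  tot <- sum(populations)
  if (tot == 0) {
    message("unit has zero population; unweighted mean used")
    return(mean(point_indices))
  }
  sum(point_indices * populations) / tot
}

#' Walkability indices for a whole city
#'
#' Computes, per fishnet cell, the basic index from the cell centre and the
#' single-point index from the cell's street-form metrics, then aggregates to
#' the chosen unit level with residential (night-time) cell populations as
#' weights.
#'
#' @param city A [generate_city()] result.
#' @param level `"block"` (default) or `"community"`.
#' @param weights,decay,street Scoring tables.
#' @return List with `cells` (`cell_id`, `base_index`, `point_index`) and
#'   `units` (`unit_id`, `area_index`).
#' @export
walkscore_city <- function(city, level = c("block", "community"),
                           weights = default_facility_weights(),
                           decay = distance_decay_policy(),
                           street = street_form_decay()) {
  stopifnot(inherits(city, "synthetic_city"))
  level <- match.arg(level)
  grid <- city$grid
  base <- vapply(seq_len(nrow(grid)), function(i) {
    base_index(c(grid$x[i], grid$y[i]), city$facilities, weights, decay)
  }, numeric(1))
  pt <- point_index(base, grid$block_length_m, grid$int_density_sqmi, street)
  cells <- data.frame(cell_id = grid$cell_id, base_index = base,
                      point_index = pt)
  # residential cell population: community night-time density x cell area
  dens <- city$population$density[match(grid$community_id,
                                        city$communities$community_id), 1]
  cell_pop <- dens * grid$area_km2
  unit_col <- if (level == "block") grid$block_id else grid$community_id
  ids <- sort(unique(unit_col))
  units <- data.frame(
    unit_id = ids,
    area_index = vapply(ids, function(u) {
      sel <- unit_col == u
      suppressMessages(area_index(pt[sel], cell_pop[sel]))
    }, numeric(1)))
  list(cells = cells, units = units)
}
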