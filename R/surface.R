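#' Average a cell surface onto spatial units
#'
#' Area-weighted mean of cell values per unit. Units are aggregations of
#' fishnet cells, so with equal cell areas the unit value is the mean of its
#' member cells. A unit listed in `unit_ids` that owns no cell falls back to
#' the value of the nearest cell (by unit centroid), with a message, when
#' coordinates are supplied; otherwise it is an error.
#'
#' @param values Numeric vector (one value per cell) or matrix (cells x
#'   hours).
#' @param cell_units Unit id per cell (same order as `values` rows).
#' @param cell_areas Optional per-cell areas for the weighted mean (equal
#'   areas assumed when omitted).
#' @param unit_ids Optional complete unit id vector (defaults to the ids seen
#'   in `cell_units`).
#' @param cell_xy,unit_xy Optional two-column coordinate matrices enabling the
#'   nearest-cell fallback for empty units.
#' @return Vector or matrix of unit means, rows named by unit id.
#' @export
block_average <- function(values, cell_units, cell_areas = NULL,
                          unit_ids = NULL, cell_xy = NULL, unit_xy = NULL) {
  vm <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(vm) != length(cell_units)) {
    stop("values and cell_units length mismatch", call. = FALSE)
  }
  if (is.null(cell_areas)) cell_areas <- rep(1, nrow(vm))
  ids <- unit_ids %||% sort(unique(cell_units))
  f <- factor(cell_units, levels = ids)
  rs <- rowsum(vm * cell_areas, f)
  ra <- rowsum(cell_areas, f)
  out <- matrix(NA_real_, length(ids), ncol(vm))
  asum <- numeric(length(ids))
  hit <- match(rownames(rs), as.character(ids))
  out[hit, ] <- rs / as.vector(ra)
  asum[hit] <- ra
  empty <- which(asum == 0)
  if (length(empty)) {
    if (is.null(cell_xy) || is.null(unit_xy)) {
      stop("units with no member cell: ", paste(ids[empty], collapse = ", "),
           call. = FALSE)
    }
    message(length(empty), " unit(s) without cells: nearest-cell fallback")
    for (e in empty) {
      j <- which.min((cell_xy[, 1] - unit_xy[e, 1])^2 +
                       (cell_xy[, 2] - unit_xy[e, 2])^2)
      out[e, ] <- vm[j, ]
    }
  }
  rownames(out) <- as.character(ids)
  if (!is.matrix(values)) out[, 1] else out
}

#' Hourly PM2.5 surfaces for a synthetic city
#'
#' Runs the concentration stage end to end for a set of hours: fits the
#' geographically weighted regression on that hour's station records, predicts
#' onto the fishnet by coefficient interpolation, and (optionally) smooths the
#' fishnet predictions by ordinary kriging with a variogram refitted per hour.
#'
#' @param city A [generate_city()] result.
#' @param hours 0-based hour indices (default: all simulated hours).
#' @param bandwidth,kernel Passed to [fit_gwr()]. A numeric bandwidth skips
#'   per-hour cross-validation; `"cv"` selects it on the first hour and reuses
#'   it, since station geometry is fixed over the week.
#' @param krige_surface If TRUE (default), apply the kriging pass.
#' @param variogram `"exponential"` or `"spherical"` model for the kriging
#'   pass.
#' @return List with `conc` (cells x hours matrix, ug/m3, columns named by
#'   hour), `r2` (per-hour GWR fit), `bandwidth`, `n_clamped`.
#' @export
estimate_surfaces <- function(city, hours = NULL, bandwidth = "cv",
                              kernel = "gaussian", krige_surface = TRUE,
                              variogram = "exponential") {
  stopifnot(inherits(city, "synthetic_city"))
  hours <- hours %||% 0:(city$config$n_hours - 1L)
  grid <- city$grid
  conc <- matrix(NA_real_, nrow(grid), length(hours),
                 dimnames = list(NULL, hours))
  r2 <- setNames(numeric(length(hours)), hours)
  n_clamped <- 0L
  bw <- bandwidth
  for (k in seq_along(hours)) {
    h <- hours[k]
    st <- stations_at_hour(city, h)
    fit <- fit_gwr(st, bandwidth = bw, kernel = kernel)
    if (identical(bw, "cv")) bw <- fit$bandwidth
    gcov <- data.frame(x = grid$x, y = grid$y,
                       aod = city$covariates$aod[, h + 1L],
                       pop = city$covariates$pop[, h + 1L],
                       ndvi = grid$ndvi, road = grid$road,
                       np_dist = grid$np_dist)
    surf <- predict_grid(fit, gcov)
    n_clamped <- n_clamped + attr(surf, "n_clamped")
    vals <- surf$value
    if (krige_surface) {
      vg <- fit_variogram(grid$x, grid$y, vals, model = variogram)
      kr <- krige(grid$x, grid$y, vals, vg, grid$x, grid$y)
      vals <- pmax(kr$value, 0)
    }
    conc[, k] <- vals
    r2[k] <- fit$r2
  }
  list(conc = conc, r2 = r2, bandwidth = bw, n_clamped = n_clamped)
}
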