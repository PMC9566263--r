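# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seeds: one master seed fans out to per-component
# streams so subsystems are independently reproducible. Kept < 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 65521) * 32749 + offset) %% 2147483587L
}

# Hour indices are 0-based over the simulated week; day 0 = Monday.
hour_of_day <- function(hour) hour %% 24L

day_of_week <- function(hour) hour %/% 24L

#' Working-hour mask
#'
#' TRUE for hourly bins at which the working-age population is at its
#' workplace: weekday (Mon-Fri) bins `[8,9), ..., [17,18)`, i.e. 8 a.m. to
#' 6 p.m., ten bins per working day.
#'
#' @param hour Integer vector of 0-based hour indices (0 = Monday 00:00).
#' @return Logical vector of the same length.
#' @export
is_work_hour <- function(hour) {
  day_of_week(hour) < 5L & hour_of_day(hour) >= 8L & hour_of_day(hour) <= 17L
}

# Banded lookup with half-open bands [lo_i, lo_{i+1}).
band_value <- function(x, lo, value) {
  if (is.unsorted(lo)) stop("band lower bounds must be sorted")
  i <- findInterval(x, lo)
  if (any(i < 1L)) stop("value below the lowest band")
  value[i]
}

# Sum of random plane waves evaluated at (x, y), rescaled to [-1, 1].
# Uses the caller's RNG stream; wavelengths are fractions of the extent so the
# field is smooth at the scale of the region.
plane_wave_field <- function(x, y, extent_m, n_waves = 3,
                             wavelength_frac = c(1.2, 0.7, 0.45)) {
  f <- numeric(length(x))
  for (m in seq_len(n_waves)) {
    theta <- stats::runif(1, 0, 2 * pi)
    phi <- stats::runif(1, 0, 2 * pi)
    wl <- extent_m * wavelength_frac[((m - 1L) %% length(wavelength_frac)) + 1L]
    f <- f + sin(2 * pi * (cos(theta) * x + sin(theta) * y) / wl + phi)
  }
  mx <- max(abs(f))
  if (mx > 0) f / mx else f
}

# Largest-remainder apportionment of `total` into shares proportional to w.
apportion <- function(total, w) {
  w <- pmax(w, 0)
  if (sum(w) <= 0) stop("non-positive apportionment weights")
  raw <- total * w / sum(w)
  base <- floor(raw)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}
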