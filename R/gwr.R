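#' Geographically weighted regression of station PM2.5
#'
#' Fits, at every station location, a kernel-weighted least-squares regression
#' of observed PM2.5 on the five concentration covariates (AOD, population
#' density, NDVI, road density, distance to industry), yielding spatially
#' varying local coefficients. With an effectively infinite bandwidth the
#' local fits coincide with global OLS.
#'
#' @param stations Data frame of one hour's station records with columns `x`,
#'   `y`, `pm25` and the covariate columns.
#' @param bandwidth Kernel scale in metres, or `"cv"` to choose it by
#'   leave-one-out cross-validation over a log-spaced grid.
#' @param kernel `"gaussian"` (default) or `"bisquare"`.
#' @param covariates Covariate column names.
#' @return Object of class `gwr_fit`: per-station `coefficients` matrix
#'   (intercept first), `fitted`, `residuals`, `r2`, `bandwidth`, `kernel`,
#'   `coords`, `covariates`, and `n_ridged` (local designs stabilised by a
#'   ridge fallback).
#' @export
fit_gwr <- function(stations, bandwidth = "cv", kernel = "gaussian",
                    covariates = c("aod", "pop", "ndvi", "road", "np_dist")) {
  need <- c("x", "y", "pm25", covariates)
  miss <- setdiff(need, names(stations))
  if (length(miss)) stop("stations table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(stations)
  p <- length(covariates)
  if (n < p + 2L) {
    stop(sprintf("need at least %d stations for %d covariates", p + 2L, p),
         call. = FALSE)
  }
  coords <- as.matrix(stations[, c("x", "y")])
  if (anyDuplicated(coords)) stop("duplicate station coordinates", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(stations[, covariates, drop = FALSE]))
  y <- stations$pm25
  D <- as.matrix(stats::dist(coords))

  if (identical(bandwidth, "cv")) {
    bandwidth <- gwr_cv_bandwidth(D, X, y, kernel)
  }
  stop_if_not_scalar_number(bandwidth, "bandwidth")
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)

  B <- matrix(NA_real_, n, ncol(X), dimnames = list(NULL, colnames(X)))
  n_ridged <- 0L
  for (i in seq_len(n)) {
    w <- gwr_kernel(D[i, ], bandwidth, kernel)
    fit <- local_wls(X, y, w)
    B[i, ] <- fit$beta
    n_ridged <- n_ridged + fit$ridged
  }
  if (n_ridged > 0) {
    warning(sprintf("%d local designs were near-singular; ridge fallback used",
                    n_ridged), call. = FALSE)
  }
  fitted <- rowSums(X * B)
  residuals <- y - fitted
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(residuals^2) / tss else NA_real_
  structure(list(coefficients = B, fitted = fitted, residuals = residuals,
                 r2 = r2, bandwidth = bandwidth, kernel = kernel,
                 coords = coords, covariates = covariates,
                 n_ridged = n_ridged),
            class = "gwr_fit")
}

gwr_kernel <- function(d, bandwidth, kernel = c("gaussian", "bisquare")) {
  kernel <- match.arg(kernel)
  if (kernel == "gaussian") {
    exp(-0.5 * (d / bandwidth)^2)
  } else {
    ifelse(d < bandwidth, (1 - (d / bandwidth)^2)^2, 0)
  }
}

# Kernel-weighted least squares with a ridge fallback on near-singular
# (locally collinear) designs. The normal equations are equilibrated by the
# column norms so conditioning reflects collinearity, not covariate units.
local_wls <- function(X, y, w, rcond_tol = 1e-10) {
  XtW <- t(X * w)
  A <- XtW %*% X
  b <- XtW %*% y
  s <- sqrt(pmax(diag(A), .Machine$double.xmin))
  As <- A / tcrossprod(s)
  bs <- b / s
  ridged <- FALSE
  if (!all(is.finite(As)) || rcond(As) < rcond_tol) {
    As <- As + diag(1e-8, ncol(As))
    ridged <- TRUE
  }
  list(beta = drop(solve(As, bs)) / s, ridged = ridged)
}

# Leave-one-out CV over a log-spaced bandwidth grid; prediction at station i
# uses a fit whose kernel weight for i itself is zeroed.
gwr_cv_bandwidth <- function(D, X, y, kernel, n_bw = 12) {
  pos <- D[D > 0]
  lo <- max(stats::quantile(pos, 0.05), 1)
  hi <- 2 * max(pos)
  grid <- exp(seq(log(lo), log(hi), length.out = n_bw))
  n <- nrow(X)
  press <- vapply(grid, function(bw) {
    err <- 0
    for (i in seq_len(n)) {
      w <- gwr_kernel(D[i, ], bw, kernel)
      w[i] <- 0
      if (sum(w > 1e-12) < ncol(X)) return(Inf)
      beta <- local_wls(X, y, w)$beta
      err <- err + (y[i] - sum(X[i, ] * beta))^2
    }
    err
  }, numeric(1))
  if (all(!is.finite(press))) {
    stop("cross-validation failed for every bandwidth", call. = FALSE)
  }
  grid[which.min(press)]
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat(sprintf("gwr_fit: %d stations, kernel %s, bandwidth %.0f m, R2 = %.3f\n",
              nrow(x$coefficients), x$kernel, x$bandwidth, x$r2))
  invisible(x)
}

#' Predict PM2.5 on a covariate grid from a GWR fit
#'
#' Transfers the local coefficients from the calibration stations to the
#' fishnet cells by inverse-distance-weighted interpolation (power 2; a cell
#' colocated with a station takes that station's coefficients exactly), then
#' evaluates the local regression equation at each cell's covariates.
#' Negative predictions are clamped to zero and counted.
#'
#' @param fit A [fit_gwr()] result.
#' @param grid Data frame of cells with `x`, `y` and the fit's covariate
#'   columns.
#' @param power Inverse-distance weighting exponent.
#' @return Data frame `x`, `y`, `value` (ug/m3) with attributes
#'   `provenance = "gwr_predicted"` and `n_clamped`.
#' @export
predict_grid <- function(fit, grid, power = 2) {
  stopifnot(inherits(fit, "gwr_fit"))
  miss <- setdiff(c("x", "y", fit$covariates), names(grid))
  if (length(miss)) stop("grid lacks covariate columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  B <- idw_interpolate(fit$coords, fit$coefficients,
                       as.matrix(grid[, c("x", "y")]), power)
  Xg <- cbind(1, as.matrix(grid[, fit$covariates, drop = FALSE]))
  pred <- rowSums(Xg * B)
  n_clamped <- sum(pred < 0)
  pred <- pmax(pred, 0)
  out <- data.frame(x = grid$x, y = grid$y, value = pred)
  attr(out, "provenance") <- "gwr_predicted"
  attr(out, "n_clamped") <- n_clamped
  out
}

# IDW interpolation of a matrix of values (one row per source point) onto
# target coordinates; exact at colocated targets.
idw_interpolate <- function(src_xy, values, tgt_xy, power = 2) {
  d2 <- outer(tgt_xy[, 1], src_xy[, 1], `-`)^2 +
    outer(tgt_xy[, 2], src_xy[, 2], `-`)^2
  d <- sqrt(d2)
  W <- 1 / pmax(d, .Machine$double.eps)^power
  exact <- d < 1e-9
  hit <- rowSums(exact) > 0
  W[hit, ] <- exact[hit, , drop = FALSE]
  W <- W / rowSums(W)
  W %*% values
}
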