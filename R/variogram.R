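#' Empirical semivariogram
#'
#' Bins half squared differences of a point attribute by pair distance.
#'
#' @param x,y Point coordinates (m).
#' @param values Attribute values.
#' @param n_bins Number of equal-width lag bins.
#' @param max_lag Maximum pair distance considered; defaults to half the
#'   maximum pairwise distance.
#' @return Data frame `lag` (bin midpoint), `gamma` (semivariance), `np`
#'   (pair count); empty bins are dropped.
#' @export
empirical_variogram <- function(x, y, values, n_bins = 12, max_lag = NULL) {
  n <- length(values)
  if (n < 10) stop("need at least 10 points", call. = FALSE)
  if (length(x) != n || length(y) != n) stop("coordinate/value length mismatch")
  d <- stats::dist(cbind(x, y))
  g <- 0.5 * stats::dist(matrix(values, ncol = 1))^2
  d <- as.vector(d); g <- as.vector(g)
  if (is.null(max_lag)) max_lag <- max(d) / 2
  keep <- d <= max_lag & d > 0
  if (!any(keep)) {
    stop("max_lag is smaller than the minimum pair distance", call. = FALSE)
  }
  d <- d[keep]; g <- g[keep]
  bins <- cut(d, breaks = seq(0, max_lag, length.out = n_bins + 1),
              include.lowest = TRUE)
  out <- data.frame(
    lag = tapply(d, bins, mean),
    gamma = tapply(g, bins, mean),
    np = as.integer(table(bins)))
  out <- out[!is.na(out$gamma), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Model semivariance; gamma(0) = 0 regardless of nugget (exact interpolation).
# `range_m` is the e-folding scale for the exponential model (practical range
# about 3 * range_m) and the full range for the spherical model.
vgm_gamma <- function(h, model) {
  g <- with(model, switch(model_name,
    exponential = nugget + psill * (1 - exp(-h / range_m)),
    spherical = nugget + psill * ifelse(h >= range_m, 1,
                                        1.5 * h / range_m - 0.5 * (h / range_m)^3),
    stop("unknown variogram model: ", model$model_name)))
  g[h <= 0] <- 0
  g
}

#' Fit a variogram model by weighted least squares
#'
#' Estimates nugget, partial sill and range by minimising the pair-count
#' weighted squared deviation between the empirical and model semivariances.
#' Constant input values yield a degenerate pure-nugget model (nugget = sill
#' = 0) flagged with `pure_nugget = TRUE`.
#'
#' @param x,y,values Point data.
#' @param model `"exponential"` (default) or `"spherical"`.
#' @inheritParams empirical_variogram
#' @return Object of class `variogram_model`: `model_name`, `nugget`, `psill`,
#'   `sill` (= nugget + psill), `range_m`, `pure_nugget`, `empirical`.
#' @export
fit_variogram <- function(x, y, values, model = c("exponential", "spherical"),
                          n_bins = 12, max_lag = NULL) {
  model <- match.arg(model)
  if (length(values) < 10) stop("need at least 10 points", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(structure(list(model_name = model, nugget = 0, psill = 0, sill = 0,
                          range_m = max_lag %||% 1, pure_nugget = TRUE,
                          empirical = NULL),
                     class = "variogram_model"))
  }
  emp <- empirical_variogram(x, y, values, n_bins = n_bins, max_lag = max_lag)
  v0 <- stats::var(values)
  init <- c(nugget = max(min(emp$gamma) / 2, 0),
            psill = max(v0 - min(emp$gamma) / 2, 1e-8),
            range_m = max(emp$lag) / 3)
  obj <- function(par) {
    m <- list(model_name = model, nugget = par[1], psill = par[2],
              range_m = par[3])
    sum(emp$np * (emp$gamma - vgm_gamma(emp$lag, m))^2)
  }
  opt <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(0, 1e-10, max(emp$lag) * 1e-3),
                      upper = c(Inf, Inf, max(emp$lag) * 10))
  par <- opt$par
  structure(list(model_name = model, nugget = par[1], psill = par[2],
                 sill = par[1] + par[2], range_m = par[3],
                 pure_nugget = FALSE, empirical = emp),
            class = "variogram_model")
}

#' Construct a variogram model directly
#'
#' @param model_name `"exponential"` or `"spherical"`.
#' @param nugget,psill Non-negative nugget and partial sill.
#' @param range_m Positive range parameter (m).
#' @return A `variogram_model`.
#' @export
variogram_model <- function(model_name, nugget, psill, range_m) {
  if (nugget < 0 || psill < 0 || range_m <= 0) {
    stop("need nugget >= 0, psill >= 0, range_m > 0", call. = FALSE)
  }
  structure(list(model_name = model_name, nugget = nugget, psill = psill,
                 sill = nugget + psill, range_m = range_m,
                 pure_nugget = (nugget + psill) == 0, empirical = NULL),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s, nugget %.3g, sill %.3g, range %.0f m%s\n",
              x$model_name, x$nugget, x$sill, x$range_m,
              if (x$pure_nugget) " (pure nugget)" else ""))
  invisible(x)
}
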