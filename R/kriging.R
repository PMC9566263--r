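#' Ordinary kriging
#'
#' Solves the ordinary kriging system (Lagrange-constrained weights summing to
#' one) for each target location using a fitted semivariogram. With a zero
#' nugget the predictor is an exact interpolator: a target coincident with a
#' datum reproduces the datum. Duplicate data coordinates are collapsed to
#' their mean value before solving, with a message.
#'
#' @param x,y,values Data point coordinates (m) and values.
#' @param variogram A [variogram_model()] / [fit_variogram()] result.
#' @param target_x,target_y Prediction coordinates.
#' @param return_weights If TRUE, attach the n_points x n_targets weight
#'   matrix as attribute `weights`.
#' @return Data frame `x`, `y`, `value` with attributes
#'   `provenance = "kriged"` and `n_outside` (targets outside the data
#'   bounding box, flagged as extrapolation).
#' @export
krige <- function(x, y, values, variogram, target_x, target_y,
                  return_weights = FALSE) {
  stopifnot(inherits(variogram, "variogram_model"))
  if (length(x) != length(values) || length(y) != length(values)) {
    stop("coordinate/value length mismatch", call. = FALSE)
  }
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    message("duplicate data coordinates collapsed to their mean value")
    agg <- stats::aggregate(values, by = list(key = key), FUN = mean)
    first <- !duplicated(key)
    ord <- match(key[first], agg$key)
    x <- x[first]; y <- y[first]; values <- agg$x[ord]
  }
  n <- length(values)
  m <- length(target_x)
  n_outside <- sum(target_x < min(x) | target_x > max(x) |
                     target_y < min(y) | target_y > max(y))

  if (variogram$sill == 0) {
    # pure-nugget degenerate model: constant field, equal weights
    pred <- rep(mean(values), m)
    out <- data.frame(x = target_x, y = target_y, value = pred)
    attr(out, "provenance") <- "kriged"
    attr(out, "n_outside") <- n_outside
    if (return_weights) attr(out, "weights") <- matrix(1 / n, n, m)
    return(out)
  }

  D <- as.matrix(stats::dist(cbind(x, y)))
  A <- rbind(cbind(vgm_gamma(D, variogram), 1), c(rep(1, n), 0))
  d_t <- sqrt(outer(target_x, x, `-`)^2 + outer(target_y, y, `-`)^2)
  B <- rbind(t(vgm_gamma(d_t, variogram)), 1)
  sol <- solve(A, B)
  w <- sol[seq_len(n), , drop = FALSE]
  pred <- drop(crossprod(w, values))
  out <- data.frame(x = target_x, y = target_y, value = pred)
  attr(out, "provenance") <- "kriged"
  attr(out, "n_outside") <- n_outside
  if (return_weights) attr(out, "weights") <- w
  out
}
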