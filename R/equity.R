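#' Lorenz curve and Gini coefficient of exposure burden
#'
#' Units are sorted ascending by per-capita exposure (the weighted
#' concentration); the Lorenz curve plots cumulative population share against
#' cumulative share of the exposure burden (`pod x population`), and the Gini
#' coefficient is one minus twice the trapezoid area under the curve.
#'
#' @param exposure Per-unit per-capita exposure (pod), non-negative.
#' @param population Per-unit vulnerable population counts, non-negative,
#'   positive total.
#' @return Object of class `lorenz_result`: `x`, `y` (curve vertices starting
#'   at (0,0) and ending at (1,1)) and `gini` in `[0, 1]`.
#' @export
lorenz_gini <- function(exposure, population) {
  n <- length(exposure)
  if (length(population) != n) stop("length mismatch", call. = FALSE)
  if (any(exposure < 0) || any(population < 0)) {
    stop("exposure and population must be non-negative", call. = FALSE)
  }
  if (sum(population) <= 0) stop("total population must be positive", call. = FALSE)
  ord <- order(exposure, seq_len(n))
  p <- population[ord]
  b <- exposure[ord] * p
  x <- c(0, cumsum(p) / sum(p))
  tb <- sum(b)
  y <- if (tb > 0) c(0, cumsum(b) / tb) else x  # all-zero exposure: equality
  gini <- 1 - sum(diff(x) * (y[-1] + y[-length(y)]))
  structure(list(x = x, y = y, gini = gini), class = "lorenz_result")
}

#' @export
print.lorenz_result <- function(x, ...) {
  cat(sprintf("lorenz_result: %d units, Gini = %.3f\n", length(x$x) - 1, x$gini))
  invisible(x)
}

#' Burden share of the most-exposed population share
#'
#' Reads the Lorenz curve from the top: the share of the total exposure
#' burden borne by the `pop_share` most exposed fraction of the population
#' (a reporting view of the same curve, e.g. "40% of the group bears 80% of
#' the burden").
#'
#' @param lorenz A [lorenz_gini()] result.
#' @param pop_share Population share in (0, 1), default 0.4.
#' @return Burden share in `[0, 1]`.
#' @export
lorenz_top_share <- function(lorenz, pop_share = 0.4) {
  stopifnot(inherits(lorenz, "lorenz_result"))
  1 - stats::approx(lorenz$x, lorenz$y, xout = 1 - pop_share, ties = "ordered")$y
}

#' Spatial weights from gridded unit memberships
#'
#' Contiguity weights for units that tile the fishnet: two units are
#' neighbours if any of their cells share an edge (`rook`) or an edge or
#' corner (`queen`). The adjacency is symmetric; rows are standardised to sum
#' to one. Island units are retained with empty rows, with a warning. A
#' k-nearest-neighbour scheme on unit centroids (symmetrised by union) is the
#' fallback for point-represented units.
#'
#' @param membership Data frame `unit_id`, `row`, `col`: one row per fishnet
#'   cell. For `scheme = "knn"`, instead a data frame `unit_id`, `x`, `y` of
#'   unit centroids.
#' @param scheme `"queen"` (default), `"rook"` or `"knn"`.
#' @param k Neighbour count for `"knn"`.
#' @return Object of class `spatial_weights`: `ids`, `nb` (integer neighbour
#'   index lists) and `w` (row-standardised weight lists).
#' @export
build_weights <- function(membership, scheme = c("queen", "rook", "knn"), k = 6) {
  scheme <- match.arg(scheme)
  if (scheme == "knn") {
    ids <- membership$unit_id
    n <- length(ids)
    if (k >= n) stop("k must be smaller than the number of units", call. = FALSE)
    D <- as.matrix(stats::dist(cbind(membership$x, membership$y)))
    diag(D) <- Inf
    nb <- lapply(seq_len(n), function(i) sort(order(D[i, ])[seq_len(k)]))
    # symmetrise by union
    for (i in seq_len(n)) for (j in nb[[i]]) {
      if (!(i %in% nb[[j]])) nb[[j]] <- sort(c(nb[[j]], i))
    }
  } else {
    need <- c("unit_id", "row", "col")
    if (!all(need %in% names(membership))) {
      stop("membership needs columns unit_id, row, col", call. = FALSE)
    }
    ids <- sort(unique(membership$unit_id))
    n <- length(ids)
    unit_idx <- match(membership$unit_id, ids)
    off <- if (scheme == "rook") {
      cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
    } else {
      cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
    }
    keymax <- max(membership$col) + 2L
    key <- membership$row * keymax + membership$col
    pairs <- NULL
    for (o in seq_len(nrow(off))) {
      nk <- (membership$row + off[o, 1]) * keymax + (membership$col + off[o, 2])
      hit <- match(nk, key)
      ok <- !is.na(hit) & unit_idx != unit_idx[hit]
      if (any(ok)) pairs <- rbind(pairs, cbind(unit_idx[ok], unit_idx[hit[ok]]))
    }
    nb <- rep(list(integer(0)), n)
    if (!is.null(pairs)) {
      pairs <- unique(pairs)
      nb <- lapply(seq_len(n), function(i) sort(unique(pairs[pairs[, 1] == i, 2])))
    }
  }
  islands <- sum(lengths(nb) == 0L)
  if (islands > 0) {
    warning(islands, " island unit(s) with no neighbours retained", call. = FALSE)
  }
  w <- lapply(nb, function(j) if (length(j)) rep(1 / length(j), length(j)) else numeric(0))
  structure(list(ids = ids, nb = nb, w = w), class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d units, mean %.1f neighbours\n",
              length(x$ids), mean(lengths(x$nb))))
  invisible(x)
}

spatial_lag <- function(w, z) {
  vapply(seq_along(w$nb), function(i) {
    if (length(w$nb[[i]])) sum(w$w[[i]] * z[w$nb[[i]]]) else 0
  }, numeric(1))
}

#' Bivariate Moran's I with permutation inference
#'
#' Global and local bivariate spatial association between `x` and the spatial
#' lag of `y`. Both variables are z-standardised (population standard
#' deviation); the global statistic is `I = sum(zx * W zy) / n` with
#' row-standardised weights, and the local statistics are
#' `I_i = zx_i * (W zy)_i`, whose mean equals the global I. Inference is by
#' permutation of `y`: full permutation for the global statistic and
#' conditional permutation (holding unit i fixed, drawing its neighbours from
#' the remaining units) for the local statistics. Pseudo p-values are
#' two-sided, `(count(|I*| >= |I|) + 1) / (n_perm + 1)`; the z-score uses the
#' permutation mean and standard deviation. With `y = x` the statistic reduces
#' to univariate Moran's I.
#'
#' @param x,y Per-unit variables, non-constant.
#' @param w A [build_weights()] result.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed for the permutations (required).
#' @param local_inference If FALSE, skip the (slower) conditional local
#'   permutations; local statistics are still returned with `pseudo_p = NA`.
#' @return Object of class `bivariate_moran`: `I`, `p_value`, `z_score`,
#'   `n_perm`, `seed` and `local` (data frame `id`, `zx`, `lag_zy`,
#'   `local_i`, `pseudo_p`).
#' @export
bivariate_moran <- function(x, y, w, n_perm = 999, seed, local_inference = TRUE) {
  stopifnot(inherits(w, "spatial_weights"))
  n <- length(w$ids)
  if (length(x) != n || length(y) != n) {
    stop("variable length must match the weights", call. = FALSE)
  }
  if (missing(seed)) stop("a permutation seed is required", call. = FALSE)
  if (all(lengths(w$nb) == 0L)) {
    stop("degenerate weights: every row is empty", call. = FALSE)
  }
  sdp <- function(v) sqrt(mean((v - mean(v))^2))
  if (sdp(x) == 0 || sdp(y) == 0) {
    stop("constant variable: zero variance", call. = FALSE)
  }
  zx <- (x - mean(x)) / sdp(x)
  zy <- (y - mean(y)) / sdp(y)
  lag_zy <- spatial_lag(w, zy)
  local_i <- zx * lag_zy
  I <- sum(local_i) / n

  set.seed(seed)
  # global: zx' W zy* = sum_j (col-sum of zx-weighted W)_j zy*_j
  v <- numeric(n)
  for (i in seq_len(n)) {
    j <- w$nb[[i]]
    if (length(j)) v[j] <- v[j] + zx[i] * w$w[[i]]
  }
  I_star <- vapply(seq_len(n_perm), function(p) {
    sum(v * zy[sample.int(n)]) / n
  }, numeric(1))
  p_value <- (sum(abs(I_star) >= abs(I)) + 1) / (n_perm + 1)
  z_score <- (I - mean(I_star)) / stats::sd(I_star)

  pseudo_p <- rep(NA_real_, n)
  if (local_inference) {
    for (i in seq_len(n)) {
      ki <- length(w$nb[[i]])
      if (ki == 0L) next
      others <- zy[-i]
      wi <- w$w[[i]]
      li <- vapply(seq_len(n_perm), function(p) {
        zx[i] * sum(wi * others[sample.int(n - 1L, ki)])
      }, numeric(1))
      pseudo_p[i] <- (sum(abs(li) >= abs(local_i[i])) + 1) / (n_perm + 1)
    }
  }
  structure(list(
    I = I, p_value = p_value, z_score = z_score, n_perm = n_perm, seed = seed,
    local = data.frame(id = w$ids, zx = zx, lag_zy = lag_zy,
                       local_i = local_i, pseudo_p = pseudo_p,
                       row.names = NULL)
  ), class = "bivariate_moran")
}

#' @export
print.bivariate_moran <- function(x, ...) {
  cat(sprintf(
    "bivariate_moran: I = %.4f, z = %.2f, pseudo-p = %.4g (%d permutations)\n",
    x$I, x$z_score, x$p_value, x$n_perm))
  invisible(x)
}

#' LISA cluster labels
#'
#' Labels each unit by its quadrant in the Moran scatter of `zx` against the
#' lag of `zy` - HH (high-high), HL, LH, LL - when its local pseudo p-value is
#' at or below `alpha`, and `ns` otherwise. `alpha = 0` marks every unit
#' `ns`.
#'
#' @param result A [bivariate_moran()] with local inference.
#' @param alpha Significance level (default 0.05).
#' @return Data frame `id`, `cluster` (factor HH/HL/LH/LL/ns) with attribute
#'   `counts`.
#' @export
lisa_clusters <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "bivariate_moran"))
  loc <- result$local
  quad <- ifelse(loc$zx > 0,
                 ifelse(loc$lag_zy > 0, "HH", "HL"),
                 ifelse(loc$lag_zy > 0, "LH", "LL"))
  sig <- alpha > 0 & !is.na(loc$pseudo_p) & loc$pseudo_p <= alpha
  cluster <- factor(ifelse(sig, quad, "ns"),
                    levels = c("HH", "HL", "LH", "LL", "ns"))
  out <- data.frame(id = loc$id, cluster = cluster, row.names = NULL)
  attr(out, "counts") <- table(cluster)
  out
}
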