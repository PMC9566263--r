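#' Equal-count tertile scores
#'
#' Quantile classification into low/medium/high thirds scored 1/2/3. The
#' equal-count split is stable (ties by input order, class sizes differing by
#' at most one, remainders to the lower classes); tied values are then
#' reassigned the lowest class any member of the tie group received, so a
#' degenerate all-equal input scores 1 everywhere.
#'
#' @param values Numeric vector, length >= 3.
#' @return Integer scores in `{1, 2, 3}` in input order.
#' @export
quantile_tertiles <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values for tertiles", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  sizes <- rep(n %/% 3L, 3L)
  rem <- n %% 3L
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(values, seq_len(n))
  cls <- integer(n)
  cls[ord] <- rep(1:3, times = sizes)
  # tie rule: a tie group takes the lowest class among its members
  ave_min <- stats::ave(cls, match(values, values), FUN = min)
  as.integer(ave_min)
}

#' Hourly tertile scoring of block exposure intensities
#'
#' Assigns each hour's block exposure intensities to tertiles (one
#' classification per hour), sums the scores per block over the week, and
#' classifies the sums into final low/medium/high exposure levels by a last
#' tertile split. Row sums are bounded by `[n_hours, 3 * n_hours]`.
#'
#' @param E_mat Blocks x hours matrix of hourly exposure intensities.
#' @return List with `scores` (blocks x hours integer matrix), `sums`
#'   (per-block summed score) and `level` (final tertile 1/2/3).
#' @export
hourly_score_sum <- function(E_mat) {
  if (!is.matrix(E_mat)) stop("E_mat must be a matrix", call. = FALSE)
  if (any(!is.finite(E_mat))) {
    stop("missing hourly exposure intensities", call. = FALSE)
  }
  scores <- apply(E_mat, 2, quantile_tertiles)
  sums <- rowSums(scores)
  list(scores = scores, sums = sums, level = quantile_tertiles(sums))
}

#' Jenks natural breaks
#'
#' Exact optimal 1-D classification into `k` classes minimising the total
#' within-class sum of squared deviations, by dynamic programming over the
#' sorted values (not a k-means heuristic).
#'
#' @param values Numeric vector.
#' @param k Number of classes, `1 <= k <= length(values)`.
#' @return List with `classes` (1-based class per input value, ascending in
#'   value), `breaks` (k + 1 class edge values, first = min, last = max) and
#'   `wss` (optimal within-class sum of squares).
#' @export
jenks_breaks <- function(values, k) {
  n <- length(values)
  if (k < 1L || k > n) stop("need 1 <= k <= length(values)", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  ord <- order(values, seq_len(n))
  v <- values[ord]
  s1 <- cumsum(v)
  s2 <- cumsum(v^2)
  ssd <- function(i, j) {
    # within-class SSD of sorted v[i..j]; i may be a vector
    a1 <- s1[j] - ifelse(i > 1, s1[i - 1], 0)
    a2 <- s2[j] - ifelse(i > 1, s2[i - 1], 0)
    pmax(a2 - a1^2 / (j - i + 1), 0)
  }
  D <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  D[1, ] <- ssd(rep(1L, n), seq_len(n))
  back[1, ] <- 1L
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        i <- m:j  # class m starts at i
        tot <- D[m - 1, i - 1] + ssd(i, j)
        best <- which.min(tot)
        D[m, j] <- tot[best]
        back[m, j] <- i[best]
      }
    }
  }
  cls_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- back[m, j]
    cls_sorted[i:j] <- m
    j <- i - 1L
  }
  classes <- integer(n)
  classes[ord] <- cls_sorted
  ends <- c(which(diff(cls_sorted) == 1L), n)
  list(classes = classes, breaks = c(v[1], v[ends]), wss = D[k, n])
}

risk_levels <- c("low", "medium", "high")

combine_levels <- function(first, second) {
  paste(risk_levels[first], risk_levels[second], sep = "-")
}

# Jenks 3-classing with the degenerate constant-axis fallback (single class,
# logged), shared by both typology builders.
jenks3_or_constant <- function(values, axis) {
  if (length(unique(values)) < 3L) {
    message("degenerate ", axis, " axis: single class assigned")
    return(rep(1L, length(values)))
  }
  jenks_breaks(values, 3L)$classes
}

#' Combined block risk typology
#'
#' Crosses the tertile exposure level (from hourly scoring) with a Jenks
#' 3-classing of the block walkability index into the 3 x 3 label grid
#' ("low-low" ... "high-high"). All nine labels are possible; the observed
#' frequency table is attached (empirically fewer may occur).
#'
#' @param exposure_level Integer 1/2/3 per block (see [hourly_score_sum()]).
#' @param walk_index Block area walkability indices; blocks with a missing
#'   index are excluded, with a message.
#' @param block_ids Optional block ids.
#' @return Data frame `block_id`, `exposure_level`, `walk_level`, `label`,
#'   with attribute `freq` (observed label counts).
#' @export
classify_blocks <- function(exposure_level, walk_index,
                            block_ids = seq_along(exposure_level)) {
  if (length(exposure_level) != length(walk_index)) {
    stop("exposure and walkability vectors must align", call. = FALSE)
  }
  keep <- is.finite(walk_index)
  if (!all(keep)) {
    message(sum(!keep), " block(s) without walk index excluded")
  }
  wl <- jenks3_or_constant(walk_index[keep], "walkability")
  out <- data.frame(block_id = block_ids[keep],
                    exposure_level = risk_levels[exposure_level[keep]],
                    walk_level = risk_levels[wl],
                    label = combine_levels(exposure_level[keep], wl),
                    row.names = NULL)
  attr(out, "freq") <- table(out$label)
  out
}

#' Combined community risk typology
#'
#' Crosses a Jenks 3-classing of weighted concentration (pod) with a Jenks
#' 3-classing of the age-group proportion into nine community categories,
#' from high concentration-high proportion to low-low.
#'
#' @param pod Community weighted PM2.5 concentrations.
#' @param age_proportion Community proportion of the age group.
#' @param community_ids Optional community ids.
#' @return Data frame `community_id`, `pod_level`, `age_level`, `label`, with
#'   attribute `freq`.
#' @export
classify_communities <- function(pod, age_proportion,
                                 community_ids = seq_along(pod)) {
  if (length(pod) != length(age_proportion)) {
    stop("pod and age proportion vectors must align", call. = FALSE)
  }
  keep <- is.finite(pod) & is.finite(age_proportion)
  if (!all(keep)) message(sum(!keep), " community(ies) with missing values excluded")
  pl <- jenks3_or_constant(pod[keep], "concentration")
  al <- jenks3_or_constant(age_proportion[keep], "age-proportion")
  out <- data.frame(community_id = community_ids[keep],
                    pod_level = risk_levels[pl],
                    age_level = risk_levels[al],
                    label = combine_levels(pl, al),
                    row.names = NULL)
  attr(out, "freq") <- table(out$label)
  out
}
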