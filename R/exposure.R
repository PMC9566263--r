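#' Time-activity schedules for the three age groups
#'
#' The elderly (65+) and children (0-6) spend all hours in their residential
#' community; the working-age population (19-59) is at its workplace on
#' weekday hourly bins `[8,18)` and at home otherwise. A residual `other`
#' group (ages 7-18 and 60-64) is home-bound and only enters the population
#' fields, not the group statistics.
#'
#' @return Named list of schedules; each has an `at_work(hour)` function
#'   mapping 0-based hour indices to a logical mask.
#' @export
default_schedules <- function() {
  home <- function(hour) rep(FALSE, length(hour))
  list(
    elderly_65p = list(at_work = home),
    child_0_6 = list(at_work = home),
    worker_19_59 = list(at_work = is_work_hour),
    other = list(at_work = home)
  )
}

#' Pollution exposure intensity of a block
#'
#' Cumulative product of hourly concentration and hourly population density
#' over the hours in which concentration exceeds the threshold:
#' `E = sum_h conc_h * density_h` (ug.person/(m3.km2)), with `NT` the count of
#' counted hours. With no threshold every hour is counted.
#'
#' @param conc Hourly block concentrations, ug/m3.
#' @param density Hourly block population densities, person/km2.
#' @param threshold Concentration threshold, ug/m3, or NULL for none.
#' @return List with `E`, `NT` and `terms` (per-hour contributions).
#' @export
exposure_intensity <- function(conc, density, threshold = NULL) {
  if (length(conc) != length(density)) {
    stop("conc and density must have equal length", call. = FALSE)
  }
  if (any(density < 0)) stop("negative population density", call. = FALSE)
  counted <- if (is.null(threshold)) rep(TRUE, length(conc)) else conc > threshold
  terms <- ifelse(counted, conc * density, 0)
  list(E = sum(terms), NT = sum(counted), terms = terms)
}

#' Exposure intensity for a block matrix
#'
#' @param conc_mat,density_mat Blocks x hours matrices (aligned rows).
#' @param threshold As in [exposure_intensity()].
#' @return Data frame `block_id`, `E`, `NT`.
#' @export
exposure_intensity_blocks <- function(conc_mat, density_mat, threshold = NULL) {
  if (!all(dim(conc_mat) == dim(density_mat))) {
    stop("conc and density matrices must have identical shape", call. = FALSE)
  }
  if (any(density_mat < 0)) stop("negative population density", call. = FALSE)
  counted <- if (is.null(threshold)) {
    matrix(TRUE, nrow(conc_mat), ncol(conc_mat))
  } else conc_mat > threshold
  data.frame(block_id = rownames(conc_mat) %||% seq_len(nrow(conc_mat)),
             E = rowSums(conc_mat * density_mat * counted),
             NT = rowSums(counted), row.names = NULL)
}

#' Time-activity-weighted PM2.5 concentration per community
#'
#' For each home community, the population-weighted mean hourly concentration
#' its resident origin-destination groups experience: non-working hours at the
#' home community, working hours (per the group schedule) at the workplace
#' community. Normalisation is per day (divide by 24 x number of days), so a
#' spatially and temporally uniform concentration `c` yields `pod = c`
#' regardless of schedules.
#'
#' @param od_groups Data frame `home_id`, `work_id`, `group`, `count`.
#' @param conc Communities x hours concentration matrix with rownames the
#'   community ids.
#' @param schedules See [default_schedules()].
#' @return Data frame `community_id`, `pod` (ug/m3), `co_sum` (summed
#'   person-hours concentration outside work), `cd_sum` (at work), `pop`.
#'   Communities with zero resident population get `pod = NA` and are listed
#'   in attribute `excluded`. Workplaces missing from `conc` fall back to the
#'   home concentration (attribute `n_work_fallback`).
#' @export
weighted_concentration <- function(od_groups, conc,
                                   schedules = default_schedules()) {
  need <- c("home_id", "work_id", "group", "count")
  miss <- setdiff(need, names(od_groups))
  if (length(miss)) stop("od_groups lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(od_groups$count < 0)) stop("negative OD group count", call. = FALSE)
  ids <- rownames(conc)
  if (is.null(ids)) stop("conc must have community ids as rownames", call. = FALSE)
  H <- ncol(conc)
  hrs <- 0:(H - 1L)
  unknown <- setdiff(unique(od_groups$group), names(schedules))
  if (length(unknown)) stop("no schedule for group(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  masks <- lapply(schedules, function(s) s$at_work(hrs))

  home_chr <- as.character(od_groups$home_id)
  work_chr <- as.character(od_groups$work_id)
  if (!all(home_chr %in% ids)) stop("unknown home community id", call. = FALSE)
  n_fallback <- sum(!(work_chr %in% ids) & od_groups$count > 0)
  work_chr[!(work_chr %in% ids)] <- home_chr[!(work_chr %in% ids)]
  if (n_fallback > 0) {
    message(n_fallback,
            " OD group(s) with workplace outside the region use home concentration")
  }

  num <- setNames(numeric(length(ids)), ids)
  co <- num; cd <- num; pop <- num
  for (g in seq_len(nrow(od_groups))) {
    cnt <- od_groups$count[g]
    if (cnt == 0) next
    mask <- masks[[od_groups$group[g]]]
    hi <- home_chr[g]
    co_g <- sum(conc[hi, !mask])
    cd_g <- sum(conc[work_chr[g], mask])
    num[hi] <- num[hi] + cnt * (co_g + cd_g)
    co[hi] <- co[hi] + cnt * co_g
    cd[hi] <- cd[hi] + cnt * cd_g
    pop[hi] <- pop[hi] + cnt
  }
  pod <- ifelse(pop > 0, num / (pop * H), NA_real_)
  out <- data.frame(community_id = ids, pod = pod, co_sum = co, cd_sum = cd,
                    pop = pop, row.names = NULL)
  excluded <- ids[pop == 0]
  if (length(excluded)) {
    message(length(excluded), " community(ies) with zero population excluded")
  }
  attr(out, "excluded") <- excluded
  attr(out, "n_work_fallback") <- n_fallback
  out
}

#' Static residence-only mean concentration
#'
#' The conventional baseline: the time mean of each community's own
#' concentration series, ignoring mobility.
#'
#' @param conc Communities x hours matrix with community-id rownames.
#' @return Data frame `community_id`, `static_mean`.
#' @export
static_exposure <- function(conc) {
  if (is.null(rownames(conc))) {
    stop("conc must have community ids as rownames", call. = FALSE)
  }
  data.frame(community_id = rownames(conc), static_mean = rowMeans(conc),
             row.names = NULL)
}

#' Population-weighted dynamic vs static regional means
#'
#' @param pod_df A [weighted_concentration()] result.
#' @param static_df A [static_exposure()] result.
#' @return List `dynamic`, `static` (ug/m3), weighted by resident population;
#'   zero-population communities are excluded from both means.
#' @export
exposure_means <- function(pod_df, static_df) {
  m <- merge(pod_df, static_df, by = "community_id")
  keep <- m$pop > 0 & is.finite(m$pod)
  list(dynamic = sum(m$pod[keep] * m$pop[keep]) / sum(m$pop[keep]),
       static = sum(m$static_mean[keep] * m$pop[keep]) / sum(m$pop[keep]))
}

#' Decile profile of weighted concentration by age composition
#'
#' Communities are sorted ascending by the proportion of the age group and
#' split into `n_groups` equal-count bins (remainders to the lowest bins);
#' per-bin weighted concentration is the population-weighted mean pod.
#'
#' @param pod Community weighted concentrations.
#' @param proportion Community proportion of the age group.
#' @param population Community resident counts (weights).
#' @param n_groups Number of bins (default 10 deciles).
#' @return Data frame `decile` (D1..Dn), `n`, `mean_pod`.
#' @export
decile_exposure <- function(pod, proportion, population = rep(1, length(pod)),
                            n_groups = 10) {
  keep <- is.finite(pod)
  pod <- pod[keep]; proportion <- proportion[keep]
  population <- population[keep]
  n <- length(pod)
  if (n < n_groups) {
    stop(sprintf("need at least %d communities with valid pod", n_groups),
         call. = FALSE)
  }
  ord <- order(proportion, seq_len(n))
  sizes <- rep(n %/% n_groups, n_groups)
  rem <- n %% n_groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin <- rep(seq_len(n_groups), times = sizes)
  idx <- split(ord, bin)
  data.frame(
    decile = paste0("D", seq_len(n_groups)),
    n = sizes,
    mean_pod = vapply(idx, function(i) {
      stats::weighted.mean(pod[i], population[i])
    }, numeric(1)),
    row.names = NULL)
}
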