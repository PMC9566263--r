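#' Pipeline configuration
#'
#' Assembles the configuration for the full analysis: synthetic-city
#' generation, hourly concentration surfaces, mobility-aware exposure,
#' walkability, risk classification and equity statistics. A single master
#' seed fans out to per-stage substreams.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master integer seed.
#' @param city Named list of [city_config()] overrides.
#' @param surface List: `bandwidth` (`"cv"` or metres), `kernel`, `krige`
#'   (logical), `variogram` model name.
#' @param exposure List: `threshold` (ug/m3 or NULL).
#' @param walkscore List: `weights`, `decay`, `street` tables.
#' @param equity List: `scheme`, `n_perm`, `alpha`, `groups` (subset of
#'   `"elderly"`, `"children"`).
#' @param stages Character vector of stages to run, in dependency order.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = file.path(tempdir(), "aerequity-run"),
                            seed = 7L,
                            city = list(), surface = list(), exposure = list(),
                            walkscore = list(), equity = list(),
                            stages = c("simulate", "surface", "exposure",
                                       "walkscore", "classify", "equity")) {
  if (is.null(city$seed)) city$seed <- derive_seed(seed, 11L)
  cc <- do.call(city_config, city)
  surface <- utils::modifyList(
    list(bandwidth = "cv", kernel = "gaussian", krige = TRUE,
         variogram = "exponential"), surface)
  exposure <- utils::modifyList(list(threshold = NULL), exposure)
  walkscore <- utils::modifyList(
    list(weights = default_facility_weights(),
         decay = distance_decay_policy(),
         street = street_form_decay()), walkscore)
  equity <- utils::modifyList(
    list(scheme = "queen", n_perm = 999L, alpha = 0.05,
         groups = c("elderly", "children")), equity)
  structure(list(out_dir = out_dir, seed = as.integer(seed), city = cc,
                 surface = surface, exposure = exposure,
                 walkscore = walkscore, equity = equity, stages = stages),
            class = "pipeline_config")
}

pipeline_stage_order <- c("simulate", "surface", "exposure", "walkscore",
                          "classify", "equity")

#' Validate a pipeline configuration
#'
#' Checks a configuration object or a YAML file against the pipeline
#' invariants: known stages, contiguous and monotone decay bands, street-form
#' tables capped at 5% each, a seed whenever permutation inference is
#' enabled, and valid city parameters. Unknown keys are warned about.
#'
#' @param config A `pipeline_config`, a plain named list, or the path of a
#'   YAML file.
#' @return List with `ok`, `errors`, `warnings`.
#' @export
validate_config <- function(config) {
  warnings <- character(0)
  if (is.character(config)) {
    if (!file.exists(config)) {
      return(list(ok = FALSE,
                  errors = paste0("config file not found: '", config, "'"),
                  warnings = warnings))
    }
    parsed <- tryCatch(yaml::read_yaml(config), error = function(e) e)
    if (inherits(parsed, "error")) {
      return(list(ok = FALSE,
                  errors = paste0("cannot parse '", config, "': ",
                                  conditionMessage(parsed)),
                  warnings = warnings))
    }
    config <- parsed
  }
  if (!inherits(config, "pipeline_config")) {
    known <- c("out_dir", "seed", "city", "surface", "exposure", "walkscore",
               "equity", "stages")
    extra <- setdiff(names(config), known)
    if (length(extra)) {
      warnings <- c(warnings, paste("unknown config keys ignored:",
                                    paste(extra, collapse = ", ")))
    }
    config <- tryCatch(do.call(pipeline_config, config[intersect(names(config), known)]),
                       error = function(e) e)
    if (inherits(config, "error")) {
      return(list(ok = FALSE, errors = conditionMessage(config),
                  warnings = warnings))
    }
  }
  errors <- character(0)
  bad <- setdiff(config$stages, pipeline_stage_order)
  if (length(bad)) {
    errors <- c(errors, paste("unknown stage(s):", paste(bad, collapse = ", ")))
  }
  errors <- c(errors, validate_decay_policy(config$walkscore$decay))
  for (tab in names(config$walkscore$street)) {
    t <- config$walkscore$street[[tab]]
    if (max(t$decay) > 0.05 + 1e-12) {
      errors <- c(errors, paste0("street-form table '", tab,
                                 "' decays beyond 5%"))
    }
  }
  if ("equity" %in% config$stages && config$equity$n_perm > 0 &&
      (is.null(config$seed) || !is.finite(config$seed))) {
    errors <- c(errors, "a seed is required when permutation inference is enabled")
  }
  list(ok = length(errors) == 0L, errors = errors, warnings = warnings)
}

stage_error <- function(artifact, producer) {
  stop(sprintf("missing %s: run the '%s' stage first", artifact, producer),
       call. = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing every stage's
#' outputs to `config$out_dir`. Stages not run in this invocation read their
#' inputs from files written by an earlier run into the same directory, and
#' fail with an error naming the producing stage when those are absent.
#'
#' @param config A [pipeline_config()].
#' @param stages Stages to run (default: those enabled in the config).
#' @return Object of class `run_manifest`: configuration hash, stages run and
#'   per-file MD5 checksums (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, stages = config$stages) {
  stopifnot(inherits(config, "pipeline_config"))
  chk <- validate_config(config)
  if (!chk$ok) stop("invalid config: ", paste(chk$errors, collapse = "; "),
                    call. = FALSE)
  stages <- pipeline_stage_order[pipeline_stage_order %in% stages]
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())

  for (stage in stages) {
    switch(stage,
      simulate = stage_simulate(config, state, out),
      surface = stage_surface(config, state, out),
      exposure = stage_exposure(config, state, out),
      walkscore = stage_walkscore(config, state, out),
      classify = stage_classify(config, state, out),
      equity = stage_equity(config, state, out))
  }

  cfg_file <- file.path(out, "pipeline_config.yaml")
  yaml::write_yaml(config_to_list(config), cfg_file, precision = 15)
  files <- sort(setdiff(list.files(out), c("manifest.json")))
  checksums <- as.list(tools::md5sum(file.path(out, files)))
  names(checksums) <- files
  manifest <- structure(list(
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = stages,
    files = checksums), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: %d stages (%s), %d files\n",
              length(x$stages), paste(x$stages, collapse = ", "),
              length(x$files)))
  invisible(x)
}

config_to_list <- function(config) {
  l <- unclass(config)
  l$out_dir <- NULL  # the analysis is path-invariant; the hash must be too
  l$city <- unclass(l$city)
  l$walkscore$weights <- as.list(l$walkscore$weights)
  l
}

## ---- stage implementations ------------------------------------------------

stage_simulate <- function(config, state, out) {
  city <- generate_city(config$city)
  state$city <- city
  res <- config$city$grid_res_m
  write_csv_q(city$stations, file.path(out, "stations.csv"))
  write_grid_geojson(city$grid, res, file.path(out, "grid.geojson"))
  write_units_geojson(city$blocks, city$grid, "block_id", res,
                      file.path(out, "blocks.geojson"))
  write_units_geojson(city$communities, city$grid, "community_id", res,
                      file.path(out, "communities.geojson"))
  write_csv_q(city$od_groups, file.path(out, "od_groups.csv"))
  write_csv_q(city$facilities, file.path(out, "facilities.csv"))
  pop_long <- matrix_to_long(city$population$counts, "community_id", "count")
  pop_long$density <- as.vector(city$population$density)
  write_csv_q(pop_long, file.path(out, "pop_hours.csv"))
  yaml::write_yaml(c(unclass(config$city),
                     list(day_mult = day_multipliers(city))),
                   file.path(out, "city_config.yaml"), precision = 15)
  invisible(state)
}

day_multipliers <- function(city) {
  # per-day AOD multipliers, recoverable from the stored hourly station AOD
  as.numeric(city$covariates$aod[1, seq(1, city$config$n_hours, by = 24)] /
               city$grid$aod_base[1])
}

need_city <- function(config, state, out) {
  if (!is.null(state$city)) return(state$city)
  if (!file.exists(file.path(out, "grid.geojson"))) {
    stage_error("the synthetic city", "simulate")
  }
  state$city <- read_city(out)
  state$city
}

#' Reload a simulated city from a pipeline output directory
#'
#' Reconstructs the in-memory city (grid, units, flows, facilities, stations,
#' hourly covariates and populations; the latent truth is not persisted) from
#' the files written by the simulate stage, enabling later stages to run in a
#' separate invocation.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return A `synthetic_city` (without `$truth`).
#' @export
read_city <- function(out_dir) {
  meta <- yaml::read_yaml(file.path(out_dir, "city_config.yaml"))
  day_mult <- as.numeric(meta$day_mult)
  meta <- meta[setdiff(names(meta), "day_mult")]
  cfg <- do.call(city_config, meta)
  grid <- read_geojson_properties(file.path(out_dir, "grid.geojson"))
  grid <- grid[order(grid$cell_id), ]
  rownames(grid) <- NULL
  blocks <- read_geojson_properties(file.path(out_dir, "blocks.geojson"))
  communities <- read_geojson_properties(file.path(out_dir, "communities.geojson"))
  od <- utils::read.csv(file.path(out_dir, "od_groups.csv"))
  facilities <- utils::read.csv(file.path(out_dir, "facilities.csv"))
  stations <- utils::read.csv(file.path(out_dir, "stations.csv"))
  pop_long <- utils::read.csv(file.path(out_dir, "pop_hours.csv"))
  counts <- long_to_matrix(pop_long, "community_id", "count")
  dens_long <- pop_long
  dens <- long_to_matrix(dens_long, "community_id", "density")
  ord <- match(communities$community_id, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  dens <- dens[ord, , drop = FALSE]
  H <- cfg$n_hours
  days <- day_of_week(0:(H - 1L))
  aod_hour <- outer(grid$aod_base, day_mult[days + 1L])
  pop_hour <- dens[match(grid$community_id, communities$community_id), ,
                   drop = FALSE]
  rownames(pop_hour) <- NULL
  structure(list(config = cfg, grid = grid, blocks = blocks,
                 communities = communities, od_groups = od,
                 facilities = facilities, stations = stations,
                 covariates = list(aod = aod_hour, pop = pop_hour),
                 population = list(counts = counts, density = dens),
                 truth = NULL),
            class = "synthetic_city")
}

stage_surface <- function(config, state, out) {
  city <- need_city(config, state, out)
  s <- config$surface
  surf <- estimate_surfaces(city, bandwidth = s$bandwidth, kernel = s$kernel,
                            krige_surface = isTRUE(s$krige),
                            variogram = s$variogram)
  state$conc <- surf$conc
  state$r2 <- surf$r2
  conc_long <- matrix_to_long(surf$conc, "cell_id", "pm25")
  conc_long$cell_id <- rep(city$grid$cell_id, times = ncol(surf$conc))
  write_csv_q(conc_long, file.path(out, "surface.csv"))
  block_conc <- block_average(surf$conc, city$grid$block_id,
                              unit_ids = city$blocks$block_id)
  state$block_conc <- block_conc
  write_csv_q(matrix_to_long(block_conc, "block_id", "pm25"),
              file.path(out, "block_pm25.csv"))
  comm_conc <- block_average(block_conc, city$blocks$community_id,
                             cell_areas = city$blocks$area_km2,
                             unit_ids = city$communities$community_id)
  state$comm_conc <- comm_conc
  write_csv_q(matrix_to_long(comm_conc, "community_id", "pm25"),
              file.path(out, "community_pm25.csv"))
  write_csv_q(data.frame(hour = as.integer(names(surf$r2)), r2 = surf$r2),
              file.path(out, "gwr_r2.csv"))
  invisible(state)
}

need_matrix <- function(state, slot, out, file, id_name, value_name, producer) {
  if (!is.null(state[[slot]])) return(state[[slot]])
  path <- file.path(out, file)
  if (!file.exists(path)) stage_error(file, producer)
  m <- long_to_matrix(utils::read.csv(path), id_name, value_name)
  state[[slot]] <- m
  m
}

stage_exposure <- function(config, state, out) {
  city <- need_city(config, state, out)
  block_conc <- need_matrix(state, "block_conc", out, "block_pm25.csv",
                            "block_id", "pm25", "surface")
  comm_conc <- need_matrix(state, "comm_conc", out, "community_pm25.csv",
                           "community_id", "pm25", "surface")
  # block density: community hourly density applied to member blocks
  dens <- city$population$density[
    match(city$blocks$community_id, city$communities$community_id), ,
    drop = FALSE]
  rownames(dens) <- rownames(block_conc)
  E <- exposure_intensity_blocks(block_conc, dens,
                                 threshold = config$exposure$threshold)
  state$E_blocks <- E
  state$block_density <- dens
  write_csv_q(E, file.path(out, "exposure_blocks.csv"))
  pod <- weighted_concentration(city$od_groups, comm_conc)
  stat <- static_exposure(comm_conc)
  pod$static_mean <- stat$static_mean[match(pod$community_id,
                                            stat$community_id)]
  state$pod <- pod
  write_csv_q(pod, file.path(out, "pod_communities.csv"))
  invisible(state)
}

stage_walkscore <- function(config, state, out) {
  city <- need_city(config, state, out)
  ws <- walkscore_city(city, level = "block",
                       weights = config$walkscore$weights,
                       decay = config$walkscore$decay,
                       street = config$walkscore$street)
  state$walk <- ws
  write_csv_q(ws$cells, file.path(out, "walkscore_points.csv"))
  names(ws$units)[1] <- "block_id"
  write_csv_q(ws$units, file.path(out, "walkscore_units.csv"))
  invisible(state)
}

need_walk <- function(state, out) {
  if (!is.null(state$walk)) return(state$walk$units)
  path <- file.path(out, "walkscore_units.csv")
  if (!file.exists(path)) stage_error("walkscore_units.csv", "walkscore")
  u <- utils::read.csv(path)
  names(u)[1] <- "unit_id"
  u
}

need_pod <- function(state, out) {
  if (!is.null(state$pod)) return(state$pod)
  path <- file.path(out, "pod_communities.csv")
  if (!file.exists(path)) stage_error("pod_communities.csv", "exposure")
  utils::read.csv(path)
}

stage_classify <- function(config, state, out) {
  city <- need_city(config, state, out)
  block_conc <- need_matrix(state, "block_conc", out, "block_pm25.csv",
                            "block_id", "pm25", "surface")
  dens <- state$block_density %||% city$population$density[
    match(city$blocks$community_id, city$communities$community_id), ,
    drop = FALSE]
  E_hourly <- block_conc * dens
  hs <- hourly_score_sum(E_hourly)
  walk <- need_walk(state, out)
  wi <- walk$area_index[match(rownames(block_conc),
                              as.character(walk$unit_id %||% walk$block_id))]
  bt <- classify_blocks(hs$level, wi, block_ids = rownames(block_conc))
  state$block_typology <- bt
  write_csv_q(bt, file.path(out, "block_typology.csv"))

  pod <- need_pod(state, out)
  comm <- city$communities
  m <- match(pod$community_id, as.character(comm$community_id))
  ct <- rbind(
    cbind(group = "elderly",
          classify_communities(pod$pod, comm$prop_65p[m], pod$community_id)),
    cbind(group = "children",
          classify_communities(pod$pod, comm$prop_0_6[m], pod$community_id)))
  state$community_typology <- ct
  write_csv_q(ct, file.path(out, "community_typology.csv"))
  invisible(state)
}

stage_equity <- function(config, state, out) {
  city <- need_city(config, state, out)
  pod <- need_pod(state, out)
  comm <- city$communities
  m <- match(as.character(comm$community_id), pod$community_id)
  podv <- pod$pod[m]
  ok <- is.finite(podv)
  membership <- data.frame(unit_id = city$grid$community_id,
                           row = city$grid$row, col = city$grid$col)
  if (config$equity$scheme == "knn") {
    membership <- data.frame(unit_id = comm$community_id,
                             x = comm$x, y = comm$y)
  }
  w <- build_weights(membership, scheme = config$equity$scheme)
  keep <- match(comm$community_id[ok], w$ids)
  if (!all(ok)) w <- subset_weights(w, keep)

  counts <- list(elderly = comm$n_elderly, children = comm$n_children)
  results <- list()
  lisa_all <- NULL
  for (gi in seq_along(config$equity$groups)) {
    g <- config$equity$groups[gi]
    cnt <- counts[[g]][ok]
    lz <- lorenz_gini(podv[ok], cnt)
    bm <- bivariate_moran(podv[ok], cnt, w, n_perm = config$equity$n_perm,
                          seed = derive_seed(config$seed, 20L + gi))
    cl <- lisa_clusters(bm, alpha = config$equity$alpha)
    results[[g]] <- list(
      gini = lz$gini,
      top40_burden_share = lorenz_top_share(lz, 0.4),
      moran_I = bm$I, z_score = bm$z_score, p_value = bm$p_value,
      n_perm = bm$n_perm,
      lisa_counts = as.list(attr(cl, "counts")))
    lisa_all <- rbind(lisa_all,
                      data.frame(community_id = cl$id, group = g,
                                 cluster = as.character(cl$cluster)))
  }
  state$equity <- results
  jsonlite::write_json(results, file.path(out, "equity.json"),
                       auto_unbox = TRUE, digits = NA)
  write_csv_q(lisa_all, file.path(out, "lisa_clusters.csv"))
  invisible(state)
}

subset_weights <- function(w, keep) {
  old2new <- match(seq_along(w$ids), keep)
  nb <- lapply(keep, function(i) {
    j <- old2new[w$nb[[i]]]
    j[!is.na(j)]
  })
  wt <- lapply(nb, function(j) {
    if (length(j)) rep(1 / length(j), length(j)) else numeric(0)
  })
  structure(list(ids = w$ids[keep], nb = nb, w = wt),
            class = "spatial_weights")
}
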