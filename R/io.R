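# Standard-format output: tabular CSV, geometries as GeoJSON in the projected
# planar CRS of the synthetic region (units metres). Cells are squares; block
# and community geometries are multipolygons of their member cells.

cell_polygon <- function(x, y, half) {
  list(list(
    c(x - half, y - half), c(x + half, y - half),
    c(x + half, y + half), c(x - half, y + half), c(x - half, y - half)))
}

geojson_features <- function(geoms, props) {
  lapply(seq_along(geoms), function(i) {
    list(type = "Feature",
         geometry = geoms[[i]],
         properties = as.list(props[i, , drop = FALSE]))
  })
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the fishnet grid as GeoJSON
#'
#' One square Polygon feature per cell; all static per-cell attributes
#' (covariates, street form, block and community membership) are carried as
#' properties.
#'
#' @param grid The `grid` element of a [generate_city()] result.
#' @param res_m Cell size, m.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_grid_geojson <- function(grid, res_m, path) {
  half <- res_m / 2
  geoms <- lapply(seq_len(nrow(grid)), function(i) {
    list(type = "Polygon", coordinates = cell_polygon(grid$x[i], grid$y[i], half))
  })
  props <- grid[, setdiff(names(grid), c("x", "y"))]
  props$x <- grid$x
  props$y <- grid$y
  write_geojson(geojson_features(geoms, props), path)
}

#' Write block or community polygons as GeoJSON
#'
#' MultiPolygon features assembled from member fishnet cells.
#'
#' @param units Unit attribute data frame (first column the unit id).
#' @param grid Fishnet grid with `x`, `y` and the membership column.
#' @param member_col Name of the membership column in `grid`.
#' @param res_m Cell size, m.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_units_geojson <- function(units, grid, member_col, res_m, path) {
  half <- res_m / 2
  id_col <- names(units)[1]
  geoms <- lapply(units[[id_col]], function(u) {
    sel <- which(grid[[member_col]] == u)
    list(type = "MultiPolygon",
         coordinates = lapply(sel, function(i) {
           cell_polygon(grid$x[i], grid$y[i], half)
         }))
  })
  write_geojson(geojson_features(geoms, units), path)
}

#' Read the properties table of a GeoJSON written by this package
#'
#' @param path GeoJSON file.
#' @return Data frame of feature properties (geometry is reconstructable from
#'   the grid coordinates and resolution, so it is not parsed).
#' @export
read_geojson_properties <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(fc$features, function(f) as.data.frame(f$properties))
  do.call(rbind, rows)
}

write_csv_q <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Long (id, hour, value) form for a units x hours matrix.
matrix_to_long <- function(m, id_name, value_name) {
  out <- data.frame(
    id = rep(rownames(m) %||% seq_len(nrow(m)), times = ncol(m)),
    hour = rep(as.integer(colnames(m) %||% (seq_len(ncol(m)) - 1L)),
               each = nrow(m)),
    value = as.vector(m))
  names(out) <- c(id_name, "hour", value_name)
  out
}

long_to_matrix <- function(df, id_name, value_name) {
  ids <- unique(df[[id_name]])
  hours <- sort(unique(df$hour))
  m <- matrix(NA_real_, length(ids), length(hours),
              dimnames = list(ids, hours))
  m[cbind(match(df[[id_name]], ids), match(df$hour, hours))] <- df[[value_name]]
  m
}
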