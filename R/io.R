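# GeoJSON (RFC 7946 structure, projected coordinates accepted) and CSV I/O.

#' Names of the sixteen link metrics, in canonical column order
#'
#' Abbreviations follow common usage in spatial design network analysis:
#' reach counts (`Links`, `Length`), angular-geodesic statistics (`NQPDA`,
#' `TPDA`, `MGLA`, `MCF`, `MAD`, `DivA`), betweenness variants (`BtA`,
#' `TPBtA`), junction counts (`Jnc`, `Con`) and convex-hull statistics
#' (`HullA`, `HullP`, `HullR`, `HullSI`).
#' @export
METRIC_NAMES <- c("Links", "Length", "NQPDA", "TPDA", "MGLA", "MCF", "MAD",
                  "DivA", "BtA", "TPBtA", "Jnc", "Con", "HullA", "HullP",
                  "HullR", "HullSI")

#' Catalog of link metrics with hypothesis tags
#'
#' Each metric carries the label of the mechanism under which it could be
#' expected to associate with community cohesion: D density, DD density
#' distribution, T twistiness, F flow, L literature (junction density),
#' E efficiency, H homogeneity.
#' @return tibble with columns `metric`, `hypothesis`, `description`
#' @export
metric_catalog <- function() {
  tibble::tribble(
    ~metric,  ~hypothesis, ~description,
    "Links",  "D",     "Number of links in radius (fractional in continuous space)",
    "Length", "D",     "Network length in radius (m)",
    "NQPDA",  "D,DD,T", "Number of links in radius penalized by angular distance to each",
    "TPDA",   "D",     "Destination popularity under the two-phase betweenness model",
    "MGLA",   "DD,T",  "Mean network length (m) of angular geodesics to all destinations in radius",
    "MCF",    "DD",    "Mean crow-flight length (m) of routes to all destinations in radius",
    "MAD",    "DD,T",  "Mean angular distance (degrees) of routes to all destinations in radius",
    "DivA",   "T",     "Mean diversion ratio: network length / crow-flight length per route",
    "BtA",    "F",     "Angular betweenness: flow prediction from angular geodesics within radius",
    "TPBtA",  "F",     "Two-phase angular betweenness: fixed trip quantity per origin",
    "Jnc",    "L",     "Junctions (nodes of degree >= 3) in radius",
    "Con",    "L",     "Total link ends joining junctions in radius",
    "HullA",  "E",     "Area (m2) of convex hull of all points reached in radius",
    "HullP",  "E",     "Perimeter (m) of convex hull",
    "HullR",  "E",     "Maximum crow-flight radius (m) of convex hull from the origin link center",
    "HullSI", "E,H",   "Circularity of convex hull: perimeter / perimeter of equal-area circle"
  )
}

#' Column name for a metric at a radius
#' @param metric metric abbreviation, see [METRIC_NAMES]
#' @param radius_m network radius in meters
#' @param continuous logical; continuous-space analysis appends the `c` suffix
#'   (e.g. `HullR600c`)
#' @return character vector of column names
#' @export
metric_column <- function(metric, radius_m, continuous = TRUE) {
  paste0(metric, radius_m, if (continuous) "c" else "")
}

geojson_coords <- function(x) {
  do.call(rbind, lapply(x, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
}

feature_id <- function(f, fallback) {
  p <- f$properties
  for (key in c("link_id", "id", "ID")) {
    if (!is.null(p[[key]])) return(as.character(p[[key]]))
    if (!is.null(f[[key]]) && key != "link_id") return(as.character(f[[key]]))
  }
  fallback
}

#' Read a road network from GeoJSON LineString features
#'
#' MultiLineString features are split into their parts with derived ids
#' (`<id>.1`, `<id>.2`, ...) and a warning, a common dialect in exported road
#' data. Coordinates must be in a projected metric CRS.
#'
#' @param path GeoJSON file
#' @param snap_tolerance_m endpoint snapping tolerance, see [build_network()]
#' @return a `spatial_network`
#' @export
read_network_geojson <- function(path, snap_tolerance_m = 0.5) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  ids <- character(0); geoms <- list(); weights <- numeric(0)
  n_multi <- 0L
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry
    id <- feature_id(f, sprintf("L%04d", i))
    w <- if (!is.null(f$properties$weight)) as.numeric(f$properties$weight) else 1
    if (identical(g$type, "LineString")) {
      ids <- c(ids, id); geoms <- c(geoms, list(geojson_coords(g$coordinates)))
      weights <- c(weights, w)
    } else if (identical(g$type, "MultiLineString")) {
      n_multi <- n_multi + 1L
      for (k in seq_along(g$coordinates)) {
        ids <- c(ids, paste0(id, ".", k))
        geoms <- c(geoms, list(geojson_coords(g$coordinates[[k]])))
        weights <- c(weights, w)
      }
    } else {
      stop("unsupported geometry type for a network feature: ", g$type)
    }
  }
  if (n_multi > 0) {
    warning(n_multi, " MultiLineString feature(s) split into parts with derived ids",
            call. = FALSE)
  }
  build_network(tibble::tibble(link_id = ids, geometry = geoms, weight = weights),
                snap_tolerance_m = snap_tolerance_m)
}

#' Write a spatial network to GeoJSON
#' @param net a `spatial_network`
#' @param path output file
#' @export
write_network_geojson <- function(net, path) {
  feats <- purrr::map2(net$links$link_id, net$links$geometry, function(id, g) {
    list(type = "Feature",
         properties = list(link_id = id),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(g)), function(i) c(g[i, 1], g[i, 2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = I(8))
  invisible(path)
}

#' Read areal units from GeoJSON Polygon features
#' @param path GeoJSON file of Polygon features; feature property `unit_id`
#'   (or `id`) identifies each unit
#' @return tibble with columns `unit_id` and `polygon` (list of ring lists;
#'   first ring exterior, others holes)
#' @export
read_units_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  ids <- character(length(feats)); polys <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry
    if (!identical(g$type, "Polygon")) {
      stop("areal units must be Polygon features; got ", g$type)
    }
    ids[i] <- feature_id(f, sprintf("U%04d", i))
    ids[i] <- if (!is.null(f$properties$unit_id)) as.character(f$properties$unit_id) else ids[i]
    polys[[i]] <- lapply(g$coordinates, geojson_coords)
  }
  if (anyDuplicated(ids)) stop("duplicate unit ids in ", path)
  tibble::tibble(unit_id = ids, polygon = polys)
}

#' Write areal units to GeoJSON
#' @param units tibble with `unit_id` and `polygon` columns
#' @param path output file
#' @export
write_units_geojson <- function(units, path) {
  feats <- purrr::map2(units$unit_id, units$polygon, function(id, rings) {
    rings <- lapply(rings, close_ring)
    list(type = "Feature",
         properties = list(unit_id = id),
         geometry = list(type = "Polygon",
                         coordinates = lapply(rings, function(r) {
                           lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
                         })))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = I(8))
  invisible(path)
}

#' Read unit outcomes from CSV
#'
#' The table must contain `unit_id`, `cohesion` (community social cohesion
#' score), `deprivation` (material deprivation score, e.g. a Townsend index)
#' and `urban` (0/1 flag).
#' @param path CSV file with a header row
#' @return tibble keyed by `unit_id`
#' @export
read_outcomes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("unit_id", "cohesion", "deprivation", "urban")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("outcomes file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df$unit_id <- as.character(df$unit_id)
  if (anyDuplicated(df$unit_id)) stop("duplicate unit_id in outcomes file")
  tibble::as_tibble(df)
}

#' Read areal units with their outcome attributes
#' @param units_path GeoJSON polygons, see [read_units_geojson()]
#' @param outcomes_path CSV, see [read_outcomes_csv()]
#' @return tibble `unit_id`, `polygon`, `cohesion`, `deprivation`, `urban`
#' @export
read_areal_units <- function(units_path, outcomes_path) {
  units <- read_units_geojson(units_path)
  out <- read_outcomes_csv(outcomes_path)
  missing <- setdiff(units$unit_id, out$unit_id)
  if (length(missing)) {
    stop("outcomes missing for unit(s): ", paste(utils::head(missing, 5), collapse = ", "))
  }
  dplyr::left_join(units, out, by = "unit_id")
}

#' Write a link metric table to CSV
#' @param rows tibble with `link_id`, `radius_m` and metric columns
#' @param path output file
#' @export
write_metrics_csv <- function(rows, path) {
  cols <- c("link_id", "radius_m", intersect(METRIC_NAMES, names(rows)))
  utils::write.csv(rows[, c(cols, setdiff(names(rows), cols))], path, row.names = FALSE)
  invisible(path)
}

#' Read a link metric table from CSV
#' @param path CSV produced by [write_metrics_csv()]
#' @return tibble
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$link_id <- as.character(df$link_id)
  tibble::as_tibble(df)
}

#' Write the aggregated unit-level analysis table to CSV
#' @param table unit-level tibble from [aggregate_metrics()]
#' @param path output file
#' @export
write_units_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
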