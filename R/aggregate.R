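# Areal aggregation: map link-level metrics onto areal units with boundary
# buffering, producing the unit-level analysis table.

#' Assign links to areal units with boundary buffering
#'
#' A link is assigned to a unit if its polyline comes within `buffer_m` of the
#' unit's polygon, equivalent to intersecting the polygon dilated by
#' `buffer_m` with round joins. Buffering keeps links that form the boundary
#' between districts counted reliably in all adjacent districts rather than
#' unreliably in only some of them; such links contribute to every unit they
#' border.
#'
#' @param units tibble with `unit_id` and `polygon` columns
#'   (see [read_units_geojson()])
#' @param net a `spatial_network`
#' @param buffer_m boundary buffer in meters (default 30)
#' @return tibble `unit_id`, `link_id` (one row per assignment); units that
#'   capture no links are absent here but retained by [aggregate_metrics()]
#'   with missing metrics
#' @export
assign_links <- function(units, net, buffer_m = 30) {
  stopifnot(buffer_m >= 0)
  link_bbox <- t(vapply(net$links$geometry, function(g) {
    c(min(g[, 1]), min(g[, 2]), max(g[, 1]), max(g[, 2]))
  }, numeric(4)))
  res <- purrr::map_dfr(seq_len(nrow(units)), function(u) {
    rings <- units$polygon[[u]]
    bb <- rings_bbox(rings)
    cand <- which(link_bbox[, 1] <= bb["xmax"] + buffer_m &
                  link_bbox[, 3] >= bb["xmin"] - buffer_m &
                  link_bbox[, 2] <= bb["ymax"] + buffer_m &
                  link_bbox[, 4] >= bb["ymin"] - buffer_m)
    hits <- cand[vapply(cand, function(i) {
      dist_polyline_polygon(net$links$geometry[[i]], rings) <= buffer_m + 1e-9
    }, logical(1))]
    tibble::tibble(unit_id = units$unit_id[u], link_id = net$links$link_id[hits])
  })
  empty <- setdiff(units$unit_id, unique(res$unit_id))
  if (length(empty)) {
    warning(length(empty), " unit(s) captured no links: ",
            paste(utils::head(empty, 5), collapse = ", "),
            if (length(empty) > 5) ", ..." else "", call. = FALSE)
  }
  res
}

#' Aggregate link metrics to areal units
#'
#' Unweighted arithmetic mean of each metric over the links assigned to each
#' unit, separately per network radius; averaging over links (not link
#' length) favours inhabited areas over uninhabited ones. Missing link-level
#' values (e.g. `HullSI` on degenerate hulls) are excluded pairwise per
#' metric. Output columns are named `<metric><radius><c?>`, e.g. `HullR600c`.
#'
#' @param assignment tibble `unit_id`, `link_id` from [assign_links()]
#' @param metric_rows link metric table from [network_metrics()]
#' @param outcomes optional tibble keyed by `unit_id` whose columns (e.g.
#'   `cohesion`, `deprivation`, `urban`) are passed through
#' @param continuous logical, only used to name the output columns; must
#'   match how `metric_rows` was computed
#' @param units optional `units` tibble; guarantees every unit appears in the
#'   output even when it captured no links
#' @return tibble: `unit_id`, `n_links`, one column per metric x radius, plus
#'   any outcome columns
#' @export
aggregate_metrics <- function(assignment, metric_rows, outcomes = NULL,
                              continuous = TRUE, units = NULL) {
  metrics_present <- intersect(METRIC_NAMES, names(metric_rows))
  joined <- dplyr::inner_join(assignment, metric_rows, by = "link_id",
                              relationship = "many-to-many")
  long <- tidyr::pivot_longer(
    joined[, c("unit_id", "link_id", "radius_m", metrics_present)],
    cols = dplyr::all_of(metrics_present),
    names_to = "metric", values_to = "value"
  )
  agg <- long |>
    dplyr::group_by(.data$unit_id, .data$radius_m, .data$metric) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value),
                  column = metric_column(.data$metric, .data$radius_m, continuous))
  wide <- tidyr::pivot_wider(agg[, c("unit_id", "column", "value")],
                             names_from = "column", values_from = "value")
  # stable column order: metric-major, radius-minor, following METRIC_NAMES
  radii <- sort(unique(metric_rows$radius_m))
  ordered_cols <- as.vector(t(outer(metrics_present, radii,
                                    function(m, r) metric_column(m, r, continuous))))
  ordered_cols <- intersect(ordered_cols, names(wide))
  n_links <- assignment |>
    dplyr::distinct(.data$unit_id, .data$link_id) |>
    dplyr::count(.data$unit_id, name = "n_links")
  out <- dplyr::left_join(n_links, wide[, c("unit_id", ordered_cols)], by = "unit_id")
  if (!is.null(units)) {
    all_units <- tibble::tibble(unit_id = units$unit_id)
    out <- dplyr::left_join(all_units, out, by = "unit_id")
    out$n_links[is.na(out$n_links)] <- 0L
  }
  if (!is.null(outcomes)) {
    out <- dplyr::left_join(out, outcomes[, setdiff(names(outcomes), "polygon")],
                            by = "unit_id")
  }
  out
}
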