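# Radial engine interface: per-link, radius-limited network analysis with
# angular geodesics, following the link-as-unit-of-analysis methodology.

match_link <- function(net, link_id) {
  i <- match(as.character(link_id), net$links$link_id)
  if (any(is.na(i))) stop("unknown link id(s): ",
                          paste(link_id[is.na(i)], collapse = ", "))
  i
}

# arc position of the analysis center of every link
origin_arcs <- function(net, mode = c("euclidean", "angular")) {
  mode <- match.arg(mode)
  vapply(seq_len(nrow(net$links)), function(i) {
    g <- net$links$geometry[[i]]
    L <- net$links$length_m[i]
    if (mode == "euclidean") return(L / 2)
    defl <- polyline_deflections(g)
    tot <- sum(defl)
    if (tot <= 0) return(L / 2)
    arcs <- polyline_cum_arc(g)[-c(1, nrow(g))]
    cum <- cumsum(defl)
    arcs[which(cum >= tot / 2 - 1e-12)[1]]
  }, numeric(1))
}

#' Analysis center of a link
#'
#' The Euclidean center is the point at half arc length; the angular center is
#' the first point along the link at which the cumulative deflection reaches
#' half the link's total angular cost (for links with no deflection it falls
#' back to the Euclidean center).
#'
#' @param net a `spatial_network`
#' @param link_id link ids (default: all links)
#' @param mode `"euclidean"` (default) or `"angular"`
#' @return tibble with `link_id`, `arc_m` (arc position of the center) and
#'   its coordinates `x`, `y`
#' @export
origin_point <- function(net, link_id = NULL, mode = c("euclidean", "angular")) {
  mode <- match.arg(mode)
  idx <- if (is.null(link_id)) seq_len(nrow(net$links)) else match_link(net, link_id)
  arcs <- origin_arcs(net, mode)[idx]
  xy <- t(vapply(seq_along(idx), function(k) {
    g <- net$links$geometry[[idx[k]]]
    interp_at_arc(g, arcs[k])
  }, numeric(2)))
  tibble::tibble(link_id = net$links$link_id[idx], arc_m = arcs,
                 x = xy[, 1], y = xy[, 2])
}

interp_at_arc <- function(g, s) {
  arc <- polyline_cum_arc(g)
  if (s <= 0) return(g[1, ])
  if (s >= arc[length(arc)]) return(g[nrow(g), ])
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  i <- min(max(i, 1), nrow(g) - 1)
  f <- (s - arc[i]) / (arc[i + 1] - arc[i])
  g[i, ] + f * (g[i + 1, ] - g[i, ])
}

#' Radius-limited reachable subsystem around one link
#'
#' Delimits the part of the network whose points lie within network distance
#' `radius_m` of the origin link's center, measured along the network (not as
#' the crow flies). In continuous-space mode each link contributes the exact
#' sub-interval(s) inside the radius, weighted by the included fraction; in
#' discrete mode a link is a member only if its entire geometry is inside
#' (the origin link is always a member).
#'
#' @param net a `spatial_network`
#' @param link_id the origin link
#' @param radius_m network radius in meters (>= 0)
#' @param continuous logical; continuous-space analysis (default TRUE)
#' @param origin_mode center type for the origin link, see [origin_point()]
#' @return object of class `radial_subsystem`: list with `members` (tibble:
#'   `link_id`, `arc_from`, `arc_to`, `P`, `full`), `origin` (point),
#'   `reached_points` (matrix), `node_dist`, `radius_m`, `continuous`
#' @export
reachable_subsystem <- function(net, link_id, radius_m, continuous = TRUE,
                                origin_mode = c("euclidean", "angular")) {
  stopifnot(radius_m >= 0)
  origin_mode <- match.arg(origin_mode)
  i <- match_link(net, link_id)
  s0 <- origin_arcs(net, origin_mode)[i]
  res <- cpp_subsystem(net_to_cpp(net), i, s0, radius_m, continuous)
  members <- tibble::tibble(
    link_id = net$links$link_id[res$link],
    arc_from = res$arc_from, arc_to = res$arc_to,
    P = res$P, full = res$full
  )
  structure(list(
    origin_link = net$links$link_id[i],
    origin = c(x = res$origin_x, y = res$origin_y, arc_m = s0),
    radius_m = radius_m, continuous = continuous,
    members = members,
    reached_points = res$reached_points,
    node_dist = res$node_dist,
    hull = res$hull
  ), class = "radial_subsystem")
}

#' @export
print.radial_subsystem <- function(x, ...) {
  cat("<radial_subsystem> origin ", x$origin_link, ", r = ", x$radius_m, " m (",
      if (x$continuous) "continuous" else "discrete", " space): ",
      nrow(x$members), " member link intervals, included length ",
      round(sum(x$members$arc_to - x$members$arc_from), 1), " m\n", sep = "")
  invisible(x)
}

#' Angular geodesics from a link to every destination in its radius
#'
#' Routes minimize cumulative angular change (deflections along link polylines
#' plus turns at junctions), restricted to the reachable subsystem. Ties in
#' angular cost are broken by network length, then hop count, then the
#' lexicographic link-id sequence, making the chosen path deterministic.
#'
#' @inheritParams reachable_subsystem
#' @return tibble with one row per destination link interval: `link_id`,
#'   `rep_arc_m` (representative point), `P` (included weight),
#'   `angular_cost_deg`, `network_length_m`, `crow_flight_m`,
#'   `diversion_ratio`, `reachable`, and `path` (list column of link-id
#'   sequences from origin to destination)
#' @export
angular_geodesics <- function(net, link_id, radius_m, continuous = TRUE,
                              origin_mode = c("euclidean", "angular")) {
  origin_mode <- match.arg(origin_mode)
  i <- match_link(net, link_id)
  s0 <- origin_arcs(net, origin_mode)[i]
  res <- cpp_geodesics(net_to_cpp(net), i, s0, radius_m, continuous)
  tibble::tibble(
    link_id = net$links$link_id[res$link],
    rep_arc_m = res$rep_arc,
    P = res$P,
    angular_cost_deg = res$angular_cost_deg,
    network_length_m = res$network_length_m,
    crow_flight_m = res$crow_flight_m,
    diversion_ratio = ifelse(res$crow_flight_m > 1e-9,
                             res$network_length_m / res$crow_flight_m, NA_real_),
    reachable = res$reachable,
    path = lapply(res$path, function(p) net$links$link_id[p])
  )
}

#' Convex-hull statistics of a reachable subsystem
#'
#' The hull is taken over all reached points (included polyline vertices plus
#' the boundary cut points at exactly the network radius). `HullR` is the
#' greatest crow-flight distance from the origin link center to any reached
#' point; `HullSI` is the circularity index HullP / (2 sqrt(pi HullA)),
#' equal to 1 for a disc. Collinear (zero-area) hulls yield `HullA = 0`,
#' `HullP` twice the maximum extent, and a missing `HullSI`.
#'
#' @param x a `radial_subsystem`, or a `spatial_network` (then `link_id` and
#'   `radius_m` must be given)
#' @param ... passed to [reachable_subsystem()] when `x` is a network
#' @return one-row tibble with `HullA` (m^2), `HullP` (m), `HullR` (m), `HullSI`
#' @export
hull_stats <- function(x, ...) {
  if (inherits(x, "spatial_network")) x <- reachable_subsystem(x, ...)
  stopifnot(inherits(x, "radial_subsystem"))
  tibble::as_tibble(as.list(x$hull))
}

#' All sixteen link metrics for every link at one or more radii
#'
#' The workhorse of the package: for each link and network radius, computes
#' reach (`Links`, `Length`), angular-geodesic statistics (`NQPDA`, `MGLA`,
#' `MCF`, `MAD`, `DivA`), junction counts (`Jnc`, `Con`), convex-hull
#' statistics (`HullA`, `HullP`, `HullR`, `HullSI`) and, over all origins,
#' the betweenness family (`BtA`, `TPBtA`, `TPDA`).
#'
#' @param net a `spatial_network`
#' @param radii network radii in meters; default the five walking scales
#'   300, 600, 900, 1200 and 1500 m
#' @param continuous logical; continuous-space analysis (default TRUE)
#' @param origin_mode link center used as analysis origin, see [origin_point()]
#' @param delta_deg floor (degrees) for the angular distance in the NQPDA
#'   denominator, preventing division by zero for collinear destinations
#' @param betweenness compute the betweenness family (requires a pass over
#'   all origins; default TRUE)
#' @return tibble with `link_id`, `radius_m`, the 16 metric columns in
#'   [METRIC_NAMES] order, and `dropped_destinations` (count of subsystem
#'   members unreachable by any in-subsystem route)
#' @export
network_metrics <- function(net, radii = c(300, 600, 900, 1200, 1500),
                            continuous = TRUE,
                            origin_mode = c("euclidean", "angular"),
                            delta_deg = 1, betweenness = TRUE) {
  origin_mode <- match.arg(origin_mode)
  stopifnot(all(radii >= 0))
  s0 <- origin_arcs(net, origin_mode)
  res <- cpp_metrics_all(net_to_cpp(net), s0, as.numeric(radii), continuous,
                         delta_deg, betweenness)
  nL <- nrow(net$links)
  local_names <- c("Links", "Length", "NQPDA", "MGLA", "MCF", "MAD", "DivA",
                   "Jnc", "Con", "HullA", "HullP", "HullR", "HullSI")
  out <- purrr::map_dfr(seq_along(radii), function(ri) {
    m <- matrix(res$metrics[, , ri, drop = FALSE], nrow = nL, ncol = 13)
    colnames(m) <- local_names
    bt <- res$betweenness[[ri]]
    df <- tibble::as_tibble(as.data.frame(m))
    df$BtA <- if (betweenness) bt$BtA else NA_real_
    df$TPBtA <- if (betweenness) bt$TPBtA else NA_real_
    df$TPDA <- if (betweenness) bt$TPDA else NA_real_
    dplyr::bind_cols(
      tibble::tibble(link_id = net$links$link_id, radius_m = radii[ri]),
      df[, METRIC_NAMES],
      tibble::tibble(dropped_destinations = res$dropped[, ri])
    )
  })
  out
}

#' Sixteen metrics for a single link
#'
#' Convenience wrapper around [network_metrics()] (the betweenness family is
#' defined over all origins, so this still runs a whole-network pass).
#' @inheritParams network_metrics
#' @param link_id the origin link
#' @param radius_m one network radius in meters
#' @return one-row tibble, see [network_metrics()]
#' @export
link_metrics <- function(net, link_id, radius_m, continuous = TRUE,
                         origin_mode = c("euclidean", "angular"),
                         delta_deg = 1, betweenness = TRUE) {
  rows <- network_metrics(net, radii = radius_m, continuous = continuous,
                          origin_mode = origin_mode, delta_deg = delta_deg,
                          betweenness = betweenness)
  rows[rows$link_id == as.character(link_id), ]
}

#' Betweenness family over the whole network
#'
#' For every origin y with surroundings R_y and every destination z in R_y,
#' each link x on the angular geodesic accrues: `BtA(x) += W(y) P(z) sigma`,
#' `TPBtA(x) += W(y) [P(z)/sum P(R_y)] sigma` (a fixed trip quantity per
#' origin distributed over in-radius destinations), and
#' `TPDA(z) += W(y) P(z)/sum P(R_y)` (destination popularity). The endpoint
#' weight sigma is 1 for strictly intermediate links, 1/2 at the origin or
#' destination, and 1/3 for the self pair.
#'
#' @inheritParams network_metrics
#' @param radius_m one network radius in meters
#' @return tibble `link_id`, `radius_m`, `BtA`, `TPBtA`, `TPDA`
#' @export
betweenness_family <- function(net, radius_m, continuous = TRUE,
                               origin_mode = c("euclidean", "angular")) {
  rows <- network_metrics(net, radii = radius_m, continuous = continuous,
                          origin_mode = origin_mode, betweenness = TRUE)
  rows[, c("link_id", "radius_m", "BtA", "TPBtA", "TPDA")]
}

#' HullR for every link across many radii (fast path)
#'
#' Computes only the convex-hull maximum radius, sharing one shortest-path
#' pass per origin across all radii; used by the radius sweep.
#' @inheritParams network_metrics
#' @return tibble `link_id`, `radius_m`, `HullR`
#' @export
hullr_profile <- function(net, radii, continuous = TRUE,
                          origin_mode = c("euclidean", "angular")) {
  origin_mode <- match.arg(origin_mode)
  s0 <- origin_arcs(net, origin_mode)
  m <- cpp_hullr_profile(net_to_cpp(net), s0, as.numeric(radii), continuous)
  purrr::map_dfr(seq_along(radii), function(ri) {
    tibble::tibble(link_id = net$links$link_id, radius_m = radii[ri],
                   HullR = m[, ri])
  })
}
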