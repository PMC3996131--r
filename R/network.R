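#' @useDynLib severance, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

# ---- polyline geometry helpers ----------------------------------------------

#' Arc length of a polyline
#' @param pts two-column matrix of projected coordinates (meters)
#' @return total Euclidean length in meters
#' @keywords internal
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Cumulative arc length at each vertex of a polyline
#' @keywords internal
polyline_cum_arc <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))))
}

#' Angle in degrees between two direction vectors (0 = same direction)
#'
#' Uses the atan2 form, which stays well-conditioned for near-collinear and
#' near-opposite vectors (acos loses ~6 digits near 0 and 180 degrees).
#' @keywords internal
vec_angle_deg <- function(u, v) {
  cross <- u[1] * v[2] - u[2] * v[1]
  dot <- sum(u * v)
  if (cross == 0 && dot == 0) return(0)
  atan2(abs(cross), dot) * 180 / pi
}

#' Deflection angles at the interior vertices of a polyline
#'
#' Deflection at a vertex is 180 degrees minus the interior angle between the
#' two adjoining segments, i.e. 0 for straight continuation and 90 for a
#' right-angle corner.
#' @keywords internal
polyline_deflections <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(numeric(0))
  vapply(seq_len(n - 2), function(i) {
    vec_angle_deg(pts[i + 1, ] - pts[i, ], pts[i + 2, ] - pts[i + 1, ])
  }, numeric(1))
}

#' Total internal angular cost of a polyline, degrees
#' @keywords internal
polyline_angular_cost <- function(pts) sum(polyline_deflections(pts))

# drop consecutive (near-)duplicate vertices
dedupe_polyline <- function(pts, tol = 1e-9) {
  if (nrow(pts) < 2) return(pts)
  keep <- c(TRUE, sqrt(rowSums((pts[-1, , drop = FALSE] -
                                  pts[-nrow(pts), , drop = FALSE])^2)) > tol)
  pts[keep, , drop = FALSE]
}

# ---- network construction ---------------------------------------------------

#' Build a spatial network from line features
#'
#' Constructs the planar link/node graph used throughout the package. Each
#' feature is one network link: the stretch of road between two adjacent
#' junctions (or a junction and a dead end), carrying its full polyline shape.
#' Endpoints closer than `snap_tolerance_m` are merged into a single node and
#' the polyline ends are snapped onto the node coordinate.
#'
#' @param line_features a data frame with columns `link_id` (unique) and
#'   `geometry` (a list of two-column coordinate matrices in a projected
#'   metric CRS), or a bare list of such matrices (ids are generated). An
#'   optional `weight` column sets per-link analysis weights (default 1).
#' @param snap_tolerance_m endpoint snapping tolerance in meters. Default
#'   0.5 m, the scale of vertex jitter in exported road data.
#' @return an object of class `spatial_network`: a list with tibbles `links`
#'   (`link_id`, `geometry`, `node_a`, `node_b`, `length_m`,
#'   `angular_cost_deg`, `weight`, `loop`) and `nodes`
#'   (`node_id`, `x`, `y`, `degree`), plus `snap_tolerance_m`.
#' @examples
#' seg <- function(x0, y0, x1, y1) cbind(c(x0, x1), c(y0, y1))
#' net <- build_network(list(seg(0, 0, 100, 0), seg(100, 0, 200, 0)))
#' net
#' @export
build_network <- function(line_features, snap_tolerance_m = 0.5) {
  if (is.data.frame(line_features)) {
    stopifnot("geometry" %in% names(line_features))
    geoms <- line_features$geometry
    ids <- if ("link_id" %in% names(line_features)) {
      as.character(line_features$link_id)
    } else sprintf("L%04d", seq_along(geoms))
    weights <- if ("weight" %in% names(line_features)) {
      as.numeric(line_features$weight)
    } else rep(1, length(geoms))
  } else if (is.list(line_features)) {
    geoms <- line_features
    ids <- sprintf("L%04d", seq_along(geoms))
    weights <- rep(1, length(geoms))
  } else {
    stop("`line_features` must be a data frame or a list of coordinate matrices")
  }
  if (anyDuplicated(ids)) stop("duplicate link ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(weights < 0)) stop("link weights must be nonnegative")

  geoms <- lapply(geoms, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    dedupe_polyline(g[, 1:2, drop = FALSE])
  })
  lens <- vapply(geoms, polyline_length, numeric(1))
  bad <- which(lens <= 0 | vapply(geoms, nrow, integer(1)) < 2)
  if (length(bad)) {
    stop("zero-length line feature(s): ", paste(ids[bad], collapse = ", "))
  }
  all_xy <- do.call(rbind, geoms)
  if (all(abs(all_xy) <= 180)) {
    warning("all coordinates lie within [-180, 180]; they look geographic, ",
            "but a projected metric CRS is required", call. = FALSE)
  }

  # snap endpoints to nodes via a grid-hash of cells of width snap_tolerance_m
  tol <- snap_tolerance_m
  node_x <- numeric(0); node_y <- numeric(0)
  cell_map <- new.env(parent = emptyenv())
  find_or_add <- function(p) {
    cw <- max(tol, 1e-9)
    cx <- floor(p[1] / cw); cy <- floor(p[2] / cw)
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(cx + dx, cy + dy, sep = "_")
      for (id in cell_map[[key]]) {
        if (sqrt((node_x[id] - p[1])^2 + (node_y[id] - p[2])^2) <= tol) return(id)
      }
    }
    node_x[length(node_x) + 1] <<- p[1]
    node_y[length(node_y) + 1] <<- p[2]
    id <- length(node_x)
    key <- paste(cx, cy, sep = "_")
    cell_map[[key]] <- c(cell_map[[key]], id)
    id
  }
  na <- integer(length(geoms)); nb <- integer(length(geoms))
  for (i in seq_along(geoms)) {
    na[i] <- find_or_add(geoms[[i]][1, ])
    nb[i] <- find_or_add(geoms[[i]][nrow(geoms[[i]]), ])
    # snap polyline ends onto the node coordinate
    geoms[[i]][1, ] <- c(node_x[na[i]], node_y[na[i]])
    geoms[[i]][nrow(geoms[[i]]), ] <- c(node_x[nb[i]], node_y[nb[i]])
    geoms[[i]] <- dedupe_polyline(geoms[[i]])
    if (nrow(geoms[[i]]) < 2 || polyline_length(geoms[[i]]) <= 0) {
      stop("feature collapsed to zero length after snapping: ", ids[i])
    }
  }
  loop <- na == nb
  if (any(loop)) {
    warning(sum(loop), " self-loop link(s) (both ends at one node): ",
            paste(ids[loop], collapse = ", "), call. = FALSE)
  }
  links <- tibble::tibble(
    link_id = ids,
    geometry = geoms,
    node_a = na,
    node_b = nb,
    length_m = vapply(geoms, polyline_length, numeric(1)),
    angular_cost_deg = vapply(geoms, polyline_angular_cost, numeric(1)),
    weight = weights,
    loop = loop
  )
  degree <- tabulate(c(na, nb), nbins = length(node_x))
  nodes <- tibble::tibble(node_id = seq_along(node_x), x = node_x, y = node_y,
                          degree = degree)
  structure(list(links = links, nodes = nodes, snap_tolerance_m = tol),
            class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat("<spatial_network> ", nrow(x$links), " links, ", nrow(x$nodes), " nodes; ",
      "total length ", format(round(sum(x$links$length_m) / 1000, 2)), " km\n", sep = "")
  cat("  node degrees: ", paste(names(table(x$nodes$degree)), table(x$nodes$degree),
                                sep = ":", collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Link table of a spatial network
#' @param net a `spatial_network`
#' @return tibble of links (one row per link)
#' @export
network_links <- function(net) {
  stopifnot(inherits(net, "spatial_network"))
  net$links
}

#' Node table of a spatial network
#' @param net a `spatial_network`
#' @return tibble of nodes with coordinates and degrees
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "spatial_network"))
  net$nodes
}

#' Connected components of a spatial network
#' @param net a `spatial_network`
#' @return integer vector: component index per link (1 = largest component)
#' @export
network_components <- function(net) {
  n <- nrow(net$nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(net$links))) {
    ra <- find(net$links$node_a[k]); rb <- find(net$links$node_b[k])
    if (ra != rb) parent[ra] <- rb
  }
  comp_node <- vapply(seq_len(n), find, integer(1))
  comp_link <- comp_node[net$links$node_a]
  sizes <- table(comp_link)
  rank <- match(comp_link, names(sort(sizes, decreasing = TRUE)))
  as.integer(rank)
}

# flat representation handed to the C++ engine
net_to_cpp <- function(net) {
  geoms <- net$links$geometry
  nv <- vapply(geoms, nrow, integer(1))
  list(
    coords = do.call(rbind, geoms),
    off = c(0L, cumsum(nv)),
    node_a = net$links$node_a - 1L,
    node_b = net$links$node_b - 1L,
    weight = net$links$weight,
    n_nodes = nrow(net$nodes),
    node_degree = net$nodes$degree
  )
}
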