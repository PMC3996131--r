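# Synthetic street networks, district partitions, and outcome generation.
# The generator produces data with the statistical structure the analysis
# assumes, so every pipeline stage is testable without survey or road data.

utf8_hash <- function(name) {
  v <- utf8ToInt(name)
  sum((v * seq_along(v)) %% 99991) %% 100003
}

substream_seed <- function(seed, name) {
  as.integer((as.numeric(seed) * 1009 + utf8_hash(name) * 7919) %% 2147480000) + 1L
}

with_substream <- function(seed, name, expr) {
  withr::with_seed(substream_seed(seed, name), expr)
}

seg2 <- function(x0, y0, x1, y1) cbind(c(x0, x1), c(y0, y1))

shift_features <- function(feats, dx, dy) {
  feats$geometry <- lapply(feats$geometry, function(g) sweep(g, 2, c(dx, dy), "+"))
  feats
}

features_tbl <- function(prefix, geoms) {
  tibble::tibble(link_id = sprintf("%s_%03d", prefix, seq_along(geoms)),
                 geometry = geoms)
}

# ---- layout families --------------------------------------------------------

#' Street layout generators
#'
#' Each family returns a tibble of line features (`link_id`, `geometry`)
#' already noded (split at junctions), ready for [build_network()]. The
#' families span the severance spectrum: `grid` and `perturbed_grid` are
#' well-connected; `zigzag` is a single winding path; `loop` is a closed
#' ring; `culdesac_estate` has tree-like interiors hanging off a winding
#' spine (high severance: little crow-flight distance gained per network
#' meter); `linear_settlement` is one long, nearly straight road with short
#' side stubs (low severance: a straight reachable ray).
#'
#' @param nx,ny node counts of the grid
#' @param spacing_m grid spacing in meters
#' @param prefix id prefix for generated links
#' @return tibble of line features
#' @name layouts
NULL

#' @rdname layouts
#' @export
gen_grid <- function(nx = 4, ny = 4, spacing_m = 100, prefix = "G") {
  geoms <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx - 1)) {
    geoms <- c(geoms, list(seg2((i - 1) * spacing_m, (j - 1) * spacing_m,
                                i * spacing_m, (j - 1) * spacing_m)))
  }
  for (j in seq_len(ny - 1)) for (i in seq_len(nx)) {
    geoms <- c(geoms, list(seg2((i - 1) * spacing_m, (j - 1) * spacing_m,
                                (i - 1) * spacing_m, j * spacing_m)))
  }
  features_tbl(prefix, geoms)
}

#' @rdname layouts
#' @param jitter_sd standard deviation (m) of Gaussian node displacement
#' @export
gen_perturbed_grid <- function(nx = 4, ny = 4, spacing_m = 100,
                               jitter_sd = spacing_m / 8, prefix = "P") {
  xs <- outer(seq_len(nx) - 1, rep(1, ny)) * spacing_m +
    matrix(stats::rnorm(nx * ny, 0, jitter_sd), nx, ny)
  ys <- outer(rep(1, nx), seq_len(ny) - 1) * spacing_m +
    matrix(stats::rnorm(nx * ny, 0, jitter_sd), nx, ny)
  geoms <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx - 1)) {
    geoms <- c(geoms, list(seg2(xs[i, j], ys[i, j], xs[i + 1, j], ys[i + 1, j])))
  }
  for (j in seq_len(ny - 1)) for (i in seq_len(nx)) {
    geoms <- c(geoms, list(seg2(xs[i, j], ys[i, j], xs[i, j + 1], ys[i, j + 1])))
  }
  features_tbl(prefix, geoms)
}

#' @rdname layouts
#' @param seg_len_m segment length (m)
#' @param n_seg number of segments
#' @param angle_deg turn at each junction (default 90, a staircase)
#' @export
gen_zigzag <- function(seg_len_m = 100, n_seg = 12, angle_deg = 90, prefix = "Z") {
  # alternating headings +/- angle/2 about east
  h1 <- (angle_deg / 2) * pi / 180
  geoms <- list()
  x <- 0; y <- 0
  for (k in seq_len(n_seg)) {
    h <- if (k %% 2 == 1) h1 else -h1
    nx <- x + seg_len_m * cos(h); ny <- y + seg_len_m * sin(h)
    geoms <- c(geoms, list(seg2(x, y, nx, ny)))
    x <- nx; y <- ny
  }
  features_tbl(prefix, geoms)
}

#' @rdname layouts
#' @param radius_m loop radius (m)
#' @param n_links number of arc links forming the ring
#' @param pts_per_link polyline vertices per arc link
#' @export
gen_loop <- function(radius_m = 200, n_links = 8, pts_per_link = 30, prefix = "O") {
  geoms <- lapply(seq_len(n_links), function(k) {
    th <- seq((k - 1) * 2 * pi / n_links, k * 2 * pi / n_links,
              length.out = pts_per_link + 1)
    cbind(radius_m * cos(th), radius_m * sin(th))
  })
  features_tbl(prefix, geoms)
}

#' @rdname layouts
#' @param spine_links links along the winding entry spine
#' @param cul_len_m length of each cul-de-sac stub (m)
#' @param n_culs number of cul-de-sacs
#' @param branch_prob probability a cul-de-sac forks into two dead ends
#' @export
gen_culdesac_estate <- function(spine_links = 5, cul_len_m = 80, n_culs = 8,
                                branch_prob = 0.4, spacing_m = 90, prefix = "C") {
  # winding spine: alternating +/-45 degree headings
  geoms <- list()
  x <- 0; y <- 0
  spine_nodes <- list(c(0, 0))
  for (k in seq_len(spine_links)) {
    h <- if (k %% 2 == 1) pi / 4 else -pi / 4
    nx <- x + spacing_m * cos(h); ny <- y + spacing_m * sin(h)
    geoms <- c(geoms, list(seg2(x, y, nx, ny)))
    x <- nx; y <- ny
    spine_nodes <- c(spine_nodes, list(c(x, y)))
  }
  # cul-de-sacs hang off spine nodes, curling back (an elbow), so they gain
  # little crow-flight distance
  for (c in seq_len(n_culs)) {
    at <- spine_nodes[[1 + (c %% (spine_links + 1))]]
    side <- if (c %% 2 == 0) 1 else -1
    base <- stats::runif(1, 0, 2 * pi)
    elbow <- at + cul_len_m * 0.6 * c(cos(base), sin(base))
    tip <- elbow + cul_len_m * 0.4 * c(cos(base + side * 2.2), sin(base + side * 2.2))
    if (stats::runif(1) < branch_prob) {
      # forked cul-de-sac: split at the elbow so the fork shares a node
      tip2 <- elbow + cul_len_m * 0.4 * c(cos(base - side * 2.2), sin(base - side * 2.2))
      geoms <- c(geoms, list(rbind(at, elbow)), list(rbind(elbow, tip)),
                 list(rbind(elbow, tip2)))
    } else {
      geoms <- c(geoms, list(rbind(at, elbow, tip)))
    }
  }
  features_tbl(prefix, geoms)
}

#' @rdname layouts
#' @param road_links links along the main road
#' @param link_len_m length of each main-road link (m)
#' @param stub_len_m length of the side stubs (m)
#' @param n_stubs number of side stubs
#' @export
gen_linear_settlement <- function(road_links = 5, link_len_m = 110,
                                  stub_len_m = 40, n_stubs = 6, prefix = "S") {
  geoms <- lapply(seq_len(road_links), function(k) {
    seg2((k - 1) * link_len_m, 0, k * link_len_m, 0)
  })
  for (s in seq_len(n_stubs)) {
    at_x <- (s %% road_links) * link_len_m
    side <- if (s %% 2 == 0) 1 else -1
    geoms <- c(geoms, list(seg2(at_x, 0, at_x, side * stub_len_m)))
  }
  features_tbl(prefix, geoms)
}

# scale + center a patch into a box [0, size] x [0, size]
fit_patch <- function(feats, size_m) {
  xy <- do.call(rbind, feats$geometry)
  rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
  span <- max(rng_x[2] - rng_x[1], rng_y[2] - rng_y[1], 1)
  s <- size_m / span
  feats$geometry <- lapply(feats$geometry, function(g) {
    cbind((g[, 1] - rng_x[1]) * s, (g[, 2] - rng_y[1]) * s)
  })
  feats
}

#' Composite synthetic borough
#'
#' Tiles an arterial grid (600 m tile edges, each edge split at its midpoint)
#' with one layout-family patch per tile, each patch joined to the arterial
#' network by a straight connector from its nearest endpoint to an edge
#' midpoint. The mixture of well-connected and severed layouts gives the
#' borough realistic between-district variation in reach metrics.
#'
#' @param tiles_x,tiles_y tile counts
#' @param tile_m tile edge length (m)
#' @param families layout families to sample from
#' @return tibble of line features
#' @export
gen_composite <- function(tiles_x = 8, tiles_y = 8, tile_m = 600,
                          families = c("grid", "perturbed_grid", "zigzag",
                                       "loop", "culdesac_estate",
                                       "linear_settlement")) {
  feats <- list()
  # arterial: tile edges as two half-links each (midpoints become junctions)
  n <- 0
  add <- function(g) { n <<- n + 1; feats[[n]] <<- g }
  for (j in 0:tiles_y) for (i in seq_len(tiles_x)) {
    x0 <- (i - 1) * tile_m; x1 <- i * tile_m; y <- j * tile_m
    add(seg2(x0, y, (x0 + x1) / 2, y)); add(seg2((x0 + x1) / 2, y, x1, y))
  }
  for (i in 0:tiles_x) for (j in seq_len(tiles_y)) {
    y0 <- (j - 1) * tile_m; y1 <- j * tile_m; x <- i * tile_m
    add(seg2(x, y0, x, (y0 + y1) / 2)); add(seg2(x, (y0 + y1) / 2, x, y1))
  }
  arterial <- tibble::tibble(link_id = sprintf("A_%04d", seq_len(n)),
                             geometry = feats)
  patches <- purrr::map_dfr(seq_len(tiles_x * tiles_y), function(t) {
    i <- (t - 1) %% tiles_x; j <- (t - 1) %/% tiles_x
    fam <- sample(families, 1)
    patch <- switch(fam,
      grid = gen_grid(5, 5, 110),
      perturbed_grid = gen_perturbed_grid(5, 5, 110, jitter_sd = 14),
      zigzag = gen_zigzag(95, 14),
      loop = gen_loop(170, 8, 24),
      culdesac_estate = gen_culdesac_estate(6, 85, 10, spacing_m = 95),
      linear_settlement = gen_linear_settlement(5, 95, 45, 6)
    )
    patch <- fit_patch(patch, tile_m - 2 * 70)
    patch <- shift_features(patch, i * tile_m + 70, j * tile_m + 70)
    patch$link_id <- sprintf("T%02d_%s", t, patch$link_id)
    # connector: nearest patch endpoint to the south edge midpoint
    mid <- c(i * tile_m + tile_m / 2, j * tile_m)
    ends <- do.call(rbind, lapply(patch$geometry, function(g) g[c(1, nrow(g)), ]))
    d2 <- (ends[, 1] - mid[1])^2 + (ends[, 2] - mid[2])^2
    best <- ends[which.min(d2), ]
    dplyr::bind_rows(patch, tibble::tibble(
      link_id = sprintf("T%02d_conn", t),
      geometry = list(seg2(best[1], best[2], mid[1], mid[2]))
    ))
  })
  dplyr::bind_rows(arterial, patches)
}

#' Generate a synthetic street network
#'
#' @param layout one of `"grid"`, `"perturbed_grid"`, `"zigzag"`, `"loop"`,
#'   `"culdesac_estate"`, `"linear_settlement"`, `"composite"`
#' @param seed integer seed; the layout draws from a dedicated substream so
#'   that, e.g., changing the district count elsewhere does not perturb the
#'   geometry
#' @param allow_disconnected keep a network whose links do not form a single
#'   connected component (default FALSE: error)
#' @param ... passed to the layout generator
#' @return a `spatial_network`
#' @export
gen_network <- function(layout = "composite", seed = 1,
                        allow_disconnected = FALSE, ...) {
  gen <- switch(layout,
    grid = gen_grid, perturbed_grid = gen_perturbed_grid, zigzag = gen_zigzag,
    loop = gen_loop, culdesac_estate = gen_culdesac_estate,
    linear_settlement = gen_linear_settlement, composite = gen_composite,
    stop("unknown layout family: ", layout))
  feats <- with_substream(seed, paste0("network_", layout), gen(...))
  net <- build_network(feats, snap_tolerance_m = 0.5)
  if (!allow_disconnected && any(network_components(net) != 1)) {
    stop("generated network is disconnected; pass allow_disconnected = TRUE ",
         "to keep it")
  }
  net
}

#' Partition the network's bounding region into districts
#'
#' Voronoi-style partition around `k` sampled link centers, computed by
#' half-plane clipping of the bounding rectangle (a geometric stand-in for
#' enumeration districts). The cells tile the bounding region exactly, so
#' every link intersects at least one district.
#'
#' @param net a `spatial_network`
#' @param k number of districts (<= number of links)
#' @param seed integer seed (dedicated substream)
#' @param margin_m bounding-box margin around the network (m)
#' @return units tibble (`unit_id`, `polygon`)
#' @export
gen_districts <- function(net, k, seed = 1, margin_m = 50) {
  stopifnot(k >= 1, k <= nrow(net$links))
  centers <- with_substream(seed, "districts", {
    idx <- sample(nrow(net$links), k)
    t(vapply(idx, function(i) {
      g <- net$links$geometry[[i]]
      interp_at_arc(g, polyline_length(g) / 2)
    }, numeric(2)))
  })
  # de-duplicate coincident seeds deterministically
  key <- paste(round(centers[, 1], 6), round(centers[, 2], 6))
  dup <- duplicated(key)
  if (any(dup)) centers[dup, ] <- centers[dup, , drop = FALSE] +
    cbind(seq_len(sum(dup)) * 1e-3, seq_len(sum(dup)) * 1e-3)
  xy <- do.call(rbind, net$links$geometry)
  bb <- c(min(xy[, 1]) - margin_m, min(xy[, 2]) - margin_m,
          max(xy[, 1]) + margin_m, max(xy[, 2]) + margin_m)
  rect <- cbind(c(bb[1], bb[3], bb[3], bb[1]), c(bb[2], bb[2], bb[4], bb[4]))
  # for each seed, clip the rectangle by bisector half-planes, nearest first
  polys <- lapply(seq_len(k), function(i) {
    p <- rect
    d2 <- (centers[, 1] - centers[i, 1])^2 + (centers[, 2] - centers[i, 2])^2
    ord <- order(d2)
    for (j in ord) {
      if (j == i) next
      # prune: bisector cannot cut if the other seed is farther than twice
      # the max distance from seed i to the current cell
      maxd2 <- max((p[, 1] - centers[i, 1])^2 + (p[, 2] - centers[i, 2])^2)
      if (d2[j] > 4 * maxd2) break
      q <- (centers[i, ] + centers[j, ]) / 2
      nvec <- centers[j, ] - centers[i, ]
      p <- clip_halfplane(p, q, nvec)
      if (nrow(p) == 0) break
    }
    list(p)
  })
  tibble::tibble(unit_id = sprintf("D%04d", seq_len(k)), polygon = polys)
}

#' Generate district-level outcomes from aggregated network metrics
#'
#' Deprivation is drawn standard normal (or, with `u_shape = TRUE`, as a
#' sign-mixed parabola in standardized HullR plus noise, so that districts
#' lowest in physical connectivity are either very poor or very rich); urban
#' status is the indicator of above-median link density; cohesion is the
#' linear model
#' \deqn{cohesion = \beta_{dep} z(deprivation) + \beta_{hull} z(HullR) +
#'   \beta_{urb} z(urban) + \epsilon}
#' with \eqn{\epsilon} scaled from the empirical variance of the linear
#' predictor so the population r-squared equals `target_r2` (the empirical
#' predictor covariance is used, not assumed orthogonality). Defaults are
#' standardized coefficients -0.42 (deprivation), +0.26 (HullR600c), -0.10
#' (urban) and r-squared 0.249.
#'
#' @param table unit table with `unit_id`, `n_links` and the hull column
#' @param units units tibble with `polygon` (for district areas / densities)
#' @param beta named vector: `deprivation`, `hull`, `urban`
#' @param target_r2 population r-squared of the cohesion model (ignored when
#'   `noise_sd` is given); must be < 1
#' @param noise_sd directly specified noise SD (0 gives a noiseless outcome)
#' @param u_shape generate the U-shaped deprivation-HullR association
#' @param beta_hull_by_tertile optional length-3 vector of HullR coefficients
#'   for the bottom, middle and top deprivation tertile (an interaction)
#' @param hull_col hull metric column (default `"HullR600c"`)
#' @param seed integer seed (dedicated substream)
#' @return tibble `unit_id`, `cohesion`, `deprivation`, `urban`
#' @export
gen_outcomes <- function(table, units,
                         beta = c(deprivation = -0.42, hull = 0.26, urban = -0.10),
                         target_r2 = 0.249, noise_sd = NULL, u_shape = FALSE,
                         beta_hull_by_tertile = NULL,
                         hull_col = "HullR600c", seed = 1) {
  stopifnot(hull_col %in% names(table), all(table$unit_id %in% units$unit_id))
  if (is.null(noise_sd) && target_r2 >= 1) {
    stop("target_r2 must be < 1 (use noise_sd = 0 for a noiseless outcome)")
  }
  k <- nrow(table)
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  hull <- table[[hull_col]]
  if (anyNA(hull)) stop("missing ", hull_col, " for ", sum(is.na(hull)), " unit(s)")
  zH <- zscore(hull)
  areas <- vapply(units$polygon[match(table$unit_id, units$unit_id)],
                  polygon_area, numeric(1))
  density <- table$n_links / pmax(areas, 1)
  with_substream(seed, "outcomes", {
    if (u_shape) {
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      deprivation <- sgn * 0.8 * (zH - 1)^2 + stats::rnorm(k, 0, 0.6)
    } else {
      deprivation <- stats::rnorm(k)
    }
    urban <- as.integer(density > stats::median(density))
    zd <- zscore(deprivation)
    zu <- if (stats::sd(urban) > 0) zscore(urban) else rep(0, k)
    bh <- rep(beta[["hull"]], k)
    if (!is.null(beta_hull_by_tertile)) {
      stopifnot(length(beta_hull_by_tertile) == 3)
      ord <- order(deprivation, table$unit_id)
      tert <- integer(k)
      tert[ord] <- ceiling(3 * seq_len(k) / k)
      bh <- beta_hull_by_tertile[tert]
    }
    y0 <- beta[["deprivation"]] * zd + bh * zH + beta[["urban"]] * zu
    sigma <- if (!is.null(noise_sd)) noise_sd else {
      stats::sd(y0) * sqrt((1 - target_r2) / target_r2)
    }
    tibble::tibble(unit_id = table$unit_id,
                   cohesion = y0 + stats::rnorm(k, 0, sigma),
                   deprivation = deprivation,
                   urban = urban)
  })
}

#' Simulate a complete synthetic study
#'
#' Generates a composite borough, partitions it into districts, computes the
#' link metrics, aggregates them, and draws outcomes — the full input set for
#' the statistical pipeline. Defaults emulate the study conditions: 325
#' districts and the default outcome model of [gen_outcomes()].
#'
#' @param seed integer seed driving all stages (named substreams)
#' @param n_units number of districts (default 325)
#' @param tiles_x,tiles_y borough size in 600 m tiles (default 8 x 8,
#'   roughly two thousand links)
#' @param radii radii for the metric table (default the five walking scales)
#' @param buffer_m aggregation buffer (default 30)
#' @param continuous continuous-space analysis (default TRUE)
#' @param betweenness compute the betweenness metrics (default TRUE)
#' @param ... passed to [gen_outcomes()]
#' @return list with `net`, `units`, `assignment`, `metric_rows`, `outcomes`
#'   and the analysis `table` (aggregated metrics + outcomes)
#' @export
simulate_severance_study <- function(seed = 1, n_units = 325,
                                     tiles_x = 8, tiles_y = 8,
                                     radii = c(300, 600, 900, 1200, 1500),
                                     buffer_m = 30, continuous = TRUE,
                                     betweenness = TRUE, ...) {
  net <- gen_network("composite", seed = seed, tiles_x = tiles_x, tiles_y = tiles_y)
  units <- gen_districts(net, n_units, seed = seed)
  assignment <- assign_links(units, net, buffer_m = buffer_m)
  metric_rows <- network_metrics(net, radii = radii, continuous = continuous,
                                 betweenness = betweenness)
  agg <- aggregate_metrics(assignment, metric_rows, continuous = continuous,
                           units = units)
  outcomes <- gen_outcomes(agg, units, seed = seed, ...)
  table <- dplyr::left_join(agg, outcomes, by = "unit_id")
  list(net = net, units = units, assignment = assignment,
       metric_rows = metric_rows, outcomes = outcomes, table = table)
}
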