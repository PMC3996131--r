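# Plain 2-D polygon primitives. A polygon is a list of rings; each ring is a
# closed or open two-column matrix (first ring = exterior, others = holes,
# even-odd rule). All coordinates are projected meters.

close_ring <- function(m) {
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

open_ring <- function(m) {
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

ring_area_signed <- function(m) {
  m <- open_ring(m)
  n <- nrow(m)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2]) / 2
}

#' Area of a polygon with holes
#' @param rings list of two-column matrices; first is the exterior ring,
#'   subsequent rings are holes
#' @return area in square meters (holes subtracted)
#' @export
polygon_area <- function(rings) {
  a <- abs(ring_area_signed(rings[[1]]))
  if (length(rings) > 1) {
    a <- a - sum(vapply(rings[-1], function(r) abs(ring_area_signed(r)), numeric(1)))
  }
  a
}

# even-odd point-in-polygon over all rings (point inside a hole => FALSE)
point_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) {
    m <- open_ring(r)
    n <- nrow(m)
    x <- m[, 1]; y <- m[, 2]
    j <- c(n, seq_len(n - 1))
    for (k in seq_len(n)) {
      xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

# squared distance from points (px, py) to segment (ax,ay)-(bx,by), vectorized
dist2_point_seg <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- ifelse(l2 > 0, ((px - ax) * dx + (py - ay) * dy) / l2, 0)
  t <- pmin(1, pmax(0, t))
  (ax + t * dx - px)^2 + (ay + t * dy - py)^2
}

seg_intersect <- function(p1, p2, p3, p4) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  (d1 * d2 < 0 && d3 * d4 < 0)
}

# minimum distance between two segments
dist_seg_seg <- function(p1, p2, p3, p4) {
  if (seg_intersect(p1, p2, p3, p4)) return(0)
  sqrt(min(
    dist2_point_seg(p1[1], p1[2], p3[1], p3[2], p4[1], p4[2]),
    dist2_point_seg(p2[1], p2[2], p3[1], p3[2], p4[1], p4[2]),
    dist2_point_seg(p3[1], p3[2], p1[1], p1[2], p2[1], p2[2]),
    dist2_point_seg(p4[1], p4[2], p1[1], p1[2], p2[1], p2[2])
  ))
}

# minimum distance from a polyline to a polygon (0 if any part lies inside);
# exact, so "within buffer_m of the polygon" == "intersects the polygon
# dilated by buffer_m with round joins"
dist_polyline_polygon <- function(pts, rings) {
  if (any(point_in_rings(pts[, 1], pts[, 2], rings))) return(0)
  # any ring vertex inside the polyline? not needed: handled by segment distances
  best <- Inf
  for (r in rings) {
    m <- close_ring(r)
    for (i in seq_len(nrow(m) - 1)) {
      a <- m[i, ]; b <- m[i + 1, ]
      # vectorized point-to-segment for all polyline vertices first (cheap bound)
      d2 <- min(dist2_point_seg(pts[, 1], pts[, 2], a[1], a[2], b[1], b[2]))
      if (d2 < best^2) best <- sqrt(d2)
      if (nrow(pts) > 1) {
        for (k in seq_len(nrow(pts) - 1)) {
          d <- dist_seg_seg(pts[k, ], pts[k + 1, ], a, b)
          if (d < best) best <- d
          if (best == 0) return(0)
        }
      }
    }
  }
  best
}

rings_bbox <- function(rings) {
  xy <- do.call(rbind, lapply(rings, open_ring))
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]), xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

# Sutherland-Hodgman clip of a convex polygon (matrix, open) by half-plane
# {p : (p - q) . n <= 0}
clip_halfplane <- function(poly, q, n) {
  np <- nrow(poly)
  if (np == 0) return(poly)
  s <- (poly[, 1] - q[1]) * n[1] + (poly[, 2] - q[2]) * n[2]
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    ins_i <- s[i] <= 0; ins_j <- s[j] <= 0
    if (ins_i) out <- rbind(out, poly[i, ])
    if (ins_i != ins_j) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}
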