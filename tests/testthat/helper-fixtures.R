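# Fixture builders shared across the suite. All constructed in code; the
# +1000 m offsets keep coordinates out of the geographic-looking range so
# build_network() does not warn.

seg2 <- function(x0, y0, x1, y1) cbind(c(x0, x1), c(y0, y1))

shift_geoms <- function(geoms, dx = 1000, dy = 1000) {
  lapply(geoms, function(g) sweep(g, 2, c(dx, dy), "+"))
}

build_quiet <- function(geoms, ...) {
  suppressWarnings(build_network(geoms, ...))
}

# straight chain of `n` 100 m links along the x axis
chain_net <- function(n = 20, len = 100) {
  xs <- seq(0, n * len, by = len)
  build_quiet(shift_geoms(lapply(seq_len(n), function(i) {
    seg2(xs[i], 0, xs[i + 1], 0)
  })))
}

# grid with nx x ny nodes
grid_net <- function(nx = 3, ny = 3, spacing = 100) {
  build_quiet(shift_geoms(gen_grid(nx, ny, spacing)$geometry))
}

# staircase: axis-aligned zigzag turning 90 degrees every `len` meters
staircase_net <- function(n = 40, len = 100) {
  geoms <- list()
  x <- 0; y <- 0
  for (k in seq_len(n)) {
    if (k %% 2 == 1) { geoms[[k]] <- seg2(x, y, x + len, y); x <- x + len }
    else { geoms[[k]] <- seg2(x, y, x, y + len); y <- y + len }
  }
  build_quiet(shift_geoms(geoms))
}

# circular loop of radius rho split into arc links
loop_net <- function(rho = 200, n_links = 8, pts = 360) {
  geoms <- lapply(seq_len(n_links), function(k) {
    th <- seq((k - 1) * 2 * pi / n_links, k * 2 * pi / n_links,
              length.out = pts + 1)
    cbind(1000 + rho * cos(th), 1000 + rho * sin(th))
  })
  build_quiet(geoms)
}

# star: four straight spokes around a short central link
star_net <- function() {
  build_quiet(shift_geoms(list(
    seg2(0, 0, 100, 0),        # center link
    seg2(0, 0, -100, 80),      # spokes at the left end
    seg2(0, 0, -100, -80),
    seg2(100, 0, 200, 80),     # spokes at the right end
    seg2(100, 0, 200, -80)
  )))
}

# random small connected network with jittered geometry (no exact ties)
random_network <- function(n_links = 10, seed = 1) {
  withr::with_seed(seed, {
    n_nodes <- sample(4:7, 1)
    n_links <- max(n_links, n_nodes - 1)
    pts <- cbind(stats::runif(n_nodes, 1000, 1500),
                 stats::runif(n_nodes, 1000, 1500))
    edges <- lapply(2:n_nodes, function(v) c(sample(v - 1, 1), v))
    while (length(edges) < n_links) {
      e <- sample(n_nodes, 2)
      edges[[length(edges) + 1]] <- e
    }
    geoms <- lapply(edges, function(e) {
      a <- pts[e[1], ]; b <- pts[e[2], ]
      if (stats::runif(1) < 0.5) rbind(a, b)
      else {
        mid <- (a + b) / 2
        d <- b - a
        perp <- c(-d[2], d[1]) / sqrt(sum(d^2))
        rbind(a, mid + perp * stats::runif(1, 5, 40), b)
      }
    })
    build_quiet(geoms)
  })
}

rect_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

expect_rel_equal <- function(got, want, tol = 1e-9) {
  both_na <- is.na(got) & is.na(want)
  g <- got[!both_na]; w <- want[!both_na]
  expect_false(any(is.na(g)) || any(is.na(w)),
               label = paste("NA mismatch:", deparse(substitute(got))))
  scale <- pmax(abs(w), 1e-6)
  expect_lt(max(abs(g - w) / scale, 0), tol)
}
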