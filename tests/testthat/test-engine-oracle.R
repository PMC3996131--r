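# Dual-route checks: the C++ engine against the pure-R brute-force reference
# (igraph split-graph distances + exhaustive path enumeration).

local_metrics_cols <- c("Links", "Length", "NQPDA", "MGLA", "MCF", "MAD",
                        "DivA", "Jnc", "Con", "HullA", "HullP", "HullR", "HullSI")

compare_all_metrics <- function(net, r, continuous, tol = 1e-9) {
  rows <- network_metrics(net, radii = r, continuous = continuous)
  orab <- oracle_betweenness(net, r, continuous)
  for (i in seq_len(nrow(net$links))) {
    got <- rows[i, ]
    want <- oracle_metrics(net, net$links$link_id[i], r, continuous)
    for (cl in local_metrics_cols) {
      g <- got[[cl]]; w <- unname(want[cl])
      if (is.na(w)) {
        expect_true(is.na(g), label = paste(cl, "origin", i, "expected NA"))
      } else {
        expect_equal(g, w, tolerance = tol, ignore_attr = TRUE,
                     label = paste(cl, "origin", i))
      }
    }
  }
  expect_equal(rows$BtA, orab$BtA, tolerance = tol)
  expect_equal(rows$TPBtA, orab$TPBtA, tolerance = tol)
  expect_equal(rows$TPDA, orab$TPDA, tolerance = tol)
}

test_that("5x5 grid, discrete space: every metric matches the brute force", {
  net <- grid_net(5, 5, 100)
  compare_all_metrics(net, 300, continuous = FALSE)
})

test_that("random networks match the brute force in both space modes", {
  for (s in 1:6) {
    net <- random_network(n_links = sample(6:11, 1, prob = rep(1, 6)) + 0, seed = s)
    compare_all_metrics(net, 250, continuous = TRUE)
    compare_all_metrics(net, 400, continuous = FALSE)
  }
})

test_that("grid cut points sit at exactly the network radius", {
  net <- grid_net(3, 3, 100)
  # origin: center of a central link
  mid <- net$links$link_id[3]  # horizontal middle-row link
  sub <- reachable_subsystem(net, mid, 150)
  d <- sqrt((sub$reached_points[, 1] - sub$origin["x"])^2 +
              (sub$reached_points[, 2] - sub$origin["y"])^2)
  expect_true(all(d <= 150 + 1e-9))
  # included length equals the split-graph oracle's
  oi <- match(mid, net$links$link_id)
  osub <- oracle_subsystem(net, oi, net$links$length_m[oi] / 2, 150, TRUE)
  expect_equal(sum(sub$members$arc_to - sub$members$arc_from),
               sum(vapply(osub$members, `[[`, numeric(1), "included_len")),
               tolerance = 1e-9)
})

test_that("reach invariants hold on random networks", {
  radii <- c(100, 200, 350, 500)
  for (s in 1:5) {
    net <- random_network(10, seed = 100 + s)
    rows <- network_metrics(net, radii = radii)
    # HullR bounded by and monotone in the radius
    expect_true(all(rows$HullR <= rows$radius_m + 1e-9))
    by_link <- split(rows, rows$link_id)
    for (b in by_link) {
      b <- b[order(b$radius_m), ]
      expect_true(all(diff(b$HullR) >= -1e-9))
    }
    ok <- !is.na(rows$DivA)
    expect_true(all(rows$DivA[ok] >= 1 - 1e-9))
    expect_true(all(rows$MAD[!is.na(rows$MAD)] >= 0))
    ok2 <- !is.na(rows$MCF) & !is.na(rows$MGLA)
    expect_true(all(rows$MCF[ok2] <= rows$MGLA[ok2] + 1e-9))
  }
})

test_that("HullR equals r exactly iff a straight reachable ray exists", {
  straight <- chain_net(20)
  expect_equal(hull_stats(straight, straight$links$link_id[10], 700)$HullR, 700,
               tolerance = 1e-12)
  stair <- staircase_net(30, 100)
  expect_lt(hull_stats(stair, stair$links$link_id[15], 600)$HullR, 600)
})

test_that("all metrics are invariant under rigid motion", {
  net <- random_network(9, seed = 42)
  rows <- network_metrics(net, radii = c(200, 400))
  th <- 0.77
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- build_quiet(tibble::tibble(
    link_id = net$links$link_id,
    geometry = lapply(net$links$geometry, function(g) {
      sweep(g %*% R, 2, c(3000, -2000), "+")
    })))
  rows2 <- network_metrics(moved, radii = c(200, 400))
  for (cl in METRIC_NAMES) {
    expect_equal(rows2[[cl]], rows[[cl]], tolerance = 1e-6,
                 label = paste("rotated", cl))
  }
})

test_that("continuous equals discrete at a saturating radius", {
  for (s in c(3, 9)) {
    net <- random_network(8, seed = 200 + s)
    rsat <- sum(net$links$length_m) + max(net$links$length_m) + 1
    mc <- network_metrics(net, radii = rsat, continuous = TRUE)
    md <- network_metrics(net, radii = rsat, continuous = FALSE)
    expect_equal(mc$Links, md$Links, tolerance = 1e-12)
    expect_equal(mc$Length, md$Length, tolerance = 1e-12)
  }
})

test_that("TPBtA totals equal the ledger total of trips times sigma", {
  net <- random_network(9, seed = 77)
  got <- betweenness_family(net, 350)
  ora <- oracle_betweenness(net, 350)
  expect_equal(sum(got$TPBtA), sum(ora$ledger$trips * ora$ledger$sigma_sum),
               tolerance = 1e-9)
})
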