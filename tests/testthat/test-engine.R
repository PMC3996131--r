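test_that("origin point: euclidean and angular centers", {
  straight <- build_quiet(list(seg2(1000, 1000, 1100, 1000)))
  expect_equal(origin_point(straight, mode = "euclidean")$arc_m, 50)
  expect_equal(origin_point(straight, mode = "angular")$arc_m, 50)

  lshape <- build_quiet(list(rbind(c(1000, 1000), c(1100, 1000), c(1100, 1100))))
  expect_equal(origin_point(lshape, mode = "euclidean")$arc_m, 100)
  expect_equal(origin_point(lshape, mode = "angular")$arc_m, 100)

  # equal 45-degree deflections at arcs 30 and 80: the angular center is the
  # first arc position where the cumulative cost reaches half the total
  d45 <- c(cos(pi / 4), sin(pi / 4))
  g <- rbind(c(0, 0), c(30, 0), c(30, 0) + 50 * d45, c(30, 0) + 50 * d45 + c(0, 40))
  two45 <- build_quiet(list(g + 1000))
  expect_equal(two45$links$angular_cost_deg, 90, tolerance = 1e-9)
  expect_equal(origin_point(two45, mode = "angular")$arc_m, 30)
})

test_that("continuous subsystem on a straight chain has symmetric extent", {
  net <- chain_net(20)  # 2 km
  mid <- net$links$link_id[10]
  sub <- reachable_subsystem(net, mid, 600)
  expect_equal(sum(sub$members$arc_to - sub$members$arc_from), 1200)
  # discrete membership: origin plus 5 whole links each way
  subd <- reachable_subsystem(net, mid, 600, continuous = FALSE)
  expect_equal(nrow(subd$members), 11)
  expect_true(all(subd$members$full[subd$members$link_id != mid]))
})

test_that("r = 0 yields a subsystem of just the origin point", {
  net <- chain_net(5)
  sub <- reachable_subsystem(net, net$links$link_id[3], 0)
  expect_equal(nrow(sub$members), 1)
  expect_equal(sub$members$arc_to - sub$members$arc_from, 0)
  hs <- hull_stats(sub)
  expect_equal(hs$HullR, 0)
  expect_equal(hs$HullA, 0)
})

test_that("angular geodesics: collinear destinations cost nothing", {
  net <- chain_net(20)
  g <- angular_geodesics(net, net$links$link_id[10], 600)
  expect_true(all(g$angular_cost_deg == 0))
  expect_equal(g$network_length_m, g$crow_flight_m, tolerance = 1e-9)
  expect_true(all(abs(g$diversion_ratio - 1) < 1e-12))
})

test_that("grid destinations requiring one turn cost 90 degrees", {
  net <- grid_net(3, 3, 100)
  # horizontal link at bottom-left; a vertical link up from its far end
  got <- angular_geodesics(net, net$links$link_id[1], 400)
  vert <- got[got$link_id == net$links$link_id[7], ]  # first vertical link
  expect_equal(vert$angular_cost_deg, 90, tolerance = 1e-9)
})

test_that("the angular geodesic can be longer in meters: bypass beats zigzag", {
  # two routes from the origin road to the destination road: a short sharp
  # staircase (283 m, 360 deg of turning) and a long gentle bypass
  # (377 m, 232 deg). The angular geodesic must take the bypass.
  geoms <- list(
    O  = seg2(-100, 0, 0, 0),
    Z1 = seg2(0, 0, 50, 50), Z2 = seg2(50, 50, 100, 0),
    Z3 = seg2(100, 0, 150, 50), Z4 = seg2(150, 50, 200, 0),
    B1 = seg2(0, 0, 100, 160), B2 = seg2(100, 160, 200, 0),
    D  = seg2(200, 0, 300, 0)
  )
  net <- build_quiet(tibble::tibble(link_id = names(geoms),
                                    geometry = shift_geoms(geoms)))
  g <- angular_geodesics(net, "O", 1500)
  dest <- g[g$link_id == "D", ]
  expect_true(all(c("B1", "B2") %in% dest$path[[1]]))
  expect_false(any(c("Z1", "Z2") %in% dest$path[[1]]))
  expect_gt(dest$network_length_m, 400)  # 377 bypass + half links
  # and it matches the exhaustive enumeration oracle
  oi <- match("O", net$links$link_id)
  sub <- oracle_subsystem(net, oi, net$links$length_m[oi] / 2, 1500, TRUE)
  ora <- oracle_geodesics(net, sub)
  od <- ora[[which(vapply(ora, `[[`, numeric(1), "e") ==
                     match("D", net$links$link_id))]]
  expect_equal(dest$angular_cost_deg, unname(od$th), tolerance = 1e-9)
  expect_equal(dest$network_length_m, unname(od$len), tolerance = 1e-9)
})

test_that("closed-form hull geometry: straight road, staircase, loop", {
  straight <- chain_net(20)
  hs <- hull_stats(straight, straight$links$link_id[10], 600)
  expect_equal(hs$HullR, 600, tolerance = 1e-9)
  expect_equal(hs$HullA, 0)
  expect_equal(hs$HullP, 2400, tolerance = 1e-9)
  expect_true(is.na(hs$HullSI))

  stair <- staircase_net(40, 100)
  mid <- stair$links$link_id[19]  # a horizontal link mid-staircase
  hz <- hull_stats(stair, mid, 600)
  expect_equal(hz$HullR, sqrt(300^2 + 300^2), tolerance = 0.01 / 424)

  loopn <- loop_net(200, 8, 360)
  hl <- hull_stats(loopn, loopn$links$link_id[1], 600)
  expect_equal(hl$HullR, 2 * 200 * sin(600 / (2 * 200)), tolerance = 0.01 / 399)
})

test_that("isolated link: counts valid, path means missing", {
  net <- build_quiet(list(seg2(1000, 1000, 1100, 1000)))
  row <- link_metrics(net, net$links$link_id[1], 300, continuous = FALSE)
  expect_equal(row$Links, 1)
  expect_true(is.na(row$MGLA) && is.na(row$MAD) && is.na(row$DivA))
  expect_equal(row$Jnc, 0)
  expect_equal(row$Con, 0)
})

test_that("straight chain: MAD = 0 and DivA = 1 exactly", {
  net <- chain_net(20)
  row <- link_metrics(net, net$links$link_id[10], 600)
  expect_equal(row$MAD, 0)
  expect_equal(row$DivA, 1)
  expect_equal(row$Links, 12)
  expect_equal(row$Length, 1200)
})

test_that("betweenness on a 3-link path matches the enumeration oracle exactly", {
  net <- build_quiet(shift_geoms(list(seg2(0, 0, 100, 0), seg2(100, 0, 200, 0),
                                      seg2(200, 0, 300, 0))))
  got <- betweenness_family(net, 1000)
  ora <- oracle_betweenness(net, 1000)
  expect_equal(got$BtA, ora$BtA, tolerance = 1e-12)
  expect_equal(got$TPBtA, ora$TPBtA, tolerance = 1e-12)
  expect_equal(got$TPDA, ora$TPDA, tolerance = 1e-12)
  # hand-derived with sigma = 1 intermediate, 1/2 endpoint, 1/3 self:
  # ends 1/3 + 4 * 1/2 = 7/3; middle 1/3 + 2 * 1 + 4 * 1/2 = 13/3
  expect_equal(got$BtA, c(7, 13, 7) / 3, tolerance = 1e-12)
})

test_that("star network: central link dominates betweenness", {
  net <- star_net()
  bt <- betweenness_family(net, 1000)
  center <- bt$BtA[bt$link_id == net$links$link_id[1]]
  spokes <- bt$BtA[bt$link_id != net$links$link_id[1]]
  expect_true(all(center > spokes))
})

test_that("per-origin trip conservation: assigned trips sum to the origin weight", {
  for (s in c(2, 7)) {
    net <- random_network(9, seed = s)
    ora <- oracle_betweenness(net, 400)
    trips <- tapply(ora$ledger$trips, ora$ledger$origin, sum)
    expect_equal(as.numeric(trips), rep(1, nrow(net$links)), tolerance = 1e-9)
    # engine TPDA totals must agree with the ledger's destination totals
    got <- betweenness_family(net, 400)
    led <- tapply(ora$ledger$trips, ora$ledger$dest, sum)
    tpda <- numeric(nrow(net$links))
    tpda[as.integer(names(led))] <- led
    expect_equal(got$TPDA, tpda, tolerance = 1e-9)
  }
})
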