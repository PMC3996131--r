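# Independent brute-force reference for the radial engine. Deliberately a
# different route than the package implementation: the reachable subsystem
# comes from igraph shortest paths on a fully split graph (every polyline
# vertex a graph vertex), and angular geodesics come from exhaustive
# enumeration of state-simple paths. Tractable for networks up to ~12 links.

o_arc <- function(g) c(0, cumsum(sqrt(rowSums((g[-1, , drop = FALSE] -
                                                 g[-nrow(g), , drop = FALSE])^2))))

o_angle <- function(u, v) {
  cross <- u[1] * v[2] - u[2] * v[1]
  dot <- sum(u * v)
  if (cross == 0 && dot == 0) return(0)
  atan2(abs(cross), dot) * 180 / pi
}

o_interp <- function(g, s) {
  arc <- o_arc(g)
  if (s <= 0) return(g[1, ])
  if (s >= arc[length(arc)]) return(g[nrow(g), ])
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  f <- (s - arc[i]) / (arc[i + 1] - arc[i])
  g[i, ] + f * (g[i + 1, ] - g[i, ])
}

# deflections at interior vertices with arc strictly inside (s, t)
o_internal <- function(g, s, t) {
  if (t < s) { tmp <- s; s <- t; t <- tmp }
  arc <- o_arc(g); m <- nrow(g)
  tot <- 0
  for (i in seq_len(m - 2) + 1) {
    if (arc[i] > s + 1e-9 && arc[i] < t - 1e-9) {
      tot <- tot + o_angle(g[i, ] - g[i - 1, ], g[i + 1, ] - g[i, ])
    }
  }
  tot
}

# split-graph distances from the origin point (arc s0 on link oi)
oracle_distances <- function(net, oi, s0) {
  vname <- function(e, i, g, node_a, node_b) {
    m <- nrow(g)
    if (i == 1) paste0("N", node_a)
    else if (i == m) paste0("N", node_b)
    else paste0("L", e, "_", i)
  }
  from <- character(0); to <- character(0); wt <- numeric(0)
  for (e in seq_len(nrow(net$links))) {
    g <- net$links$geometry[[e]]
    arc <- o_arc(g)
    names_e <- vapply(seq_len(nrow(g)), vname, character(1), e = e, g = g,
                      node_a = net$links$node_a[e], node_b = net$links$node_b[e])
    arcs_e <- arc
    if (e == oi) {
      # insert the origin vertex at arc s0 (unless it coincides with one)
      hit <- which(abs(arcs_e - s0) <= 1e-9)
      if (length(hit)) {
        names_e[hit[1]] <- paste0("ORIG|", names_e[hit[1]])
      } else {
        i <- findInterval(s0, arcs_e, rightmost.closed = TRUE)
        names_e <- append(names_e, "ORIG", after = i)
        arcs_e <- append(arcs_e, s0, after = i)
      }
    }
    for (i in seq_len(length(names_e) - 1)) {
      from <- c(from, names_e[i]); to <- c(to, names_e[i + 1])
      wt <- c(wt, arcs_e[i + 1] - arcs_e[i])
    }
  }
  gr <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = wt), directed = FALSE)
  src <- grep("^ORIG", igraph::V(gr)$name, value = TRUE)[1]
  d <- igraph::distances(gr, v = src, weights = igraph::E(gr)$weight)[1, ]
  names(d) <- sub("^ORIG\\|", "", names(d))
  d
}

union_intervals <- function(iv, tol = 1e-9) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2] + tol) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

# members, included intervals, reached points -- segment-level route
oracle_subsystem <- function(net, oi, s0, r, continuous) {
  d <- oracle_distances(net, oi, s0)
  origin_pt <- o_interp(net$links$geometry[[oi]], s0)
  members <- list()
  reached <- matrix(origin_pt, ncol = 2)
  for (e in seq_len(nrow(net$links))) {
    g <- net$links$geometry[[e]]
    arc <- o_arc(g); m <- nrow(g)
    vn <- vapply(seq_len(m), function(i) {
      if (i == 1) paste0("N", net$links$node_a[e])
      else if (i == m) paste0("N", net$links$node_b[e])
      else paste0("L", e, "_", i)
    }, character(1))
    arcs_e <- arc; dv <- unname(d[vn])
    if (e == oi) {
      hit <- which(abs(arcs_e - s0) <= 1e-9)
      if (!length(hit)) {
        i <- findInterval(s0, arcs_e, rightmost.closed = TRUE)
        arcs_e <- append(arcs_e, s0, after = i)
        dv <- append(dv, 0, after = i)
      } else dv[hit[1]] <- 0
    }
    iv <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(length(arcs_e) - 1)) {
      seg <- arcs_e[i + 1] - arcs_e[i]
      if (seg <= 0) next
      if (dv[i] <= r) {
        hi <- min(seg, r - dv[i])
        iv <- rbind(iv, c(arcs_e[i], arcs_e[i] + hi))
      }
      if (dv[i + 1] <= r) {
        lo <- max(0, seg - (r - dv[i + 1]))
        iv <- rbind(iv, c(arcs_e[i] + lo, arcs_e[i + 1]))
      }
    }
    iv <- union_intervals(iv)
    inc_len <- if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0
    L <- arc[m]
    full <- nrow(iv) == 1 && iv[1, 1] <= 1e-9 && iv[1, 2] >= L - 1e-9
    is_member <- if (continuous) inc_len > 1e-9 || e == oi else full || e == oi
    if (!is_member) next
    if (!continuous) { iv <- matrix(c(0, L), ncol = 2); inc_len <- L }
    if (continuous && !nrow(iv)) iv <- matrix(c(s0, s0), ncol = 2)
    members[[length(members) + 1]] <- list(
      e = e, full = full, ivals = iv, included_len = inc_len,
      P = if (continuous) inc_len / L * net$links$weight[e] else net$links$weight[e])
    # reached points
    if (!continuous) {
      reached <- rbind(reached, g)
    } else {
      for (k in seq_len(nrow(iv))) {
        reached <- rbind(reached, o_interp(g, iv[k, 1]), o_interp(g, iv[k, 2]))
        inside <- arc > iv[k, 1] + 1e-9 & arc < iv[k, 2] - 1e-9
        if (any(inside)) reached <- rbind(reached, g[inside, , drop = FALSE])
      }
    }
  }
  # origin first
  eidx <- vapply(members, `[[`, numeric(1), "e")
  members <- members[order(eidx != oi, eidx)]
  list(members = members, reached = reached, origin_pt = origin_pt, d = d,
       r = r, oi = oi, s0 = s0, continuous = continuous)
}

oracle_hull <- function(pts, origin_pt) {
  R <- max(sqrt((pts[, 1] - origin_pt[1])^2 + (pts[, 2] - origin_pt[2])^2))
  u <- unique(round(pts, 12))
  if (nrow(u) == 1) return(c(HullA = 0, HullP = 0, HullR = R, HullSI = NA))
  h <- u[grDevices::chull(u), , drop = FALSE]
  hn <- nrow(h)
  diam <- max(stats::dist(h))
  if (hn < 3) return(c(HullA = 0, HullP = 2 * diam, HullR = R, HullSI = NA))
  j <- c(2:hn, 1)
  area <- abs(sum(h[, 1] * h[j, 2] - h[j, 1] * h[, 2])) / 2
  per <- sum(sqrt((h[j, 1] - h[, 1])^2 + (h[j, 2] - h[, 2])^2))
  if (area < 1e-6 * max(1, diam^2)) {
    return(c(HullA = 0, HullP = 2 * diam, HullR = R, HullSI = NA))
  }
  c(HullA = area, HullP = per, HullR = R, HullSI = per / (2 * sqrt(pi * area)))
}

# composite path-cost comparator: (theta, len, hops, lex link sequence)
o_better <- function(th1, l1, p1, th2, l2, p2) {
  if (th1 < th2 - 1e-7) return(TRUE)
  if (th1 > th2 + 1e-7) return(FALSE)
  if (l1 < l2 - 1e-5) return(TRUE)
  if (l1 > l2 + 1e-5) return(FALSE)
  if (length(p1) != length(p2)) return(length(p1) < length(p2))
  cmp <- p1 - p2
  nz <- which(cmp != 0)
  if (!length(nz)) return(FALSE)
  cmp[nz[1]] < 0
}

# exhaustive enumeration of angular geodesics to every destination interval
oracle_geodesics <- function(net, sub) {
  oi <- sub$oi; s0 <- sub$s0; r <- sub$r; continuous <- sub$continuous
  mem <- sub$members
  midx <- rep(NA_integer_, nrow(net$links))
  for (i in seq_along(mem)) midx[mem[[i]]$e] <- i
  geo <- net$links$geometry
  L <- net$links$length_m
  # destination intervals
  dests <- list()
  for (i in seq_along(mem)) {
    M <- mem[[i]]
    if (M$e == oi) next
    for (k in seq_len(nrow(M$ivals))) {
      a <- M$ivals[k, 1]; b <- M$ivals[k, 2]
      rep_arc <- (a + b) / 2
      dests[[length(dests) + 1]] <- list(
        e = M$e, a = a, b = b, rep = rep_arc,
        P = if (continuous) (b - a) / L[M$e] * net$links$weight[M$e] else net$links$weight[M$e],
        th = Inf, len = Inf, path = NULL)
    }
  }
  if (!length(dests)) return(dests)
  dest_e_vec <- vapply(dests, `[[`, numeric(1), "e")
  dest_at <- function(e) which(dest_e_vec == e)
  # sound pruning bound: once every destination has some path, a branch whose
  # accumulated cost strictly exceeds the worst best-so-far cannot improve
  # any destination (costs only grow along a path; ties are kept)
  prune_bound <- function() {
    ths <- vapply(dests, `[[`, numeric(1), "th")
    if (any(is.infinite(ths))) Inf else max(ths)
  }
  # DFS over states (link, entry end)
  visit <- function(e, entry, th_in, len_in, path, visited) {
    if (th_in > prune_bound() + 1e-7) return()
    # record destinations on e reachable from this entry
    for (di in dest_at(e)) {
      D <- dests[[di]]
      touches <- if (entry == 0) D$a <= 1e-9 else D$b >= L[e] - 1e-9
      if (!touches) next
      th_d <- th_in + if (entry == 0) o_internal(geo[[e]], 0, D$rep)
                      else o_internal(geo[[e]], D$rep, L[e])
      len_d <- len_in + if (entry == 0) D$rep else L[e] - D$rep
      cur <- dests[[di]]
      if (is.null(cur$path) ||
          o_better(th_d, len_d, path, cur$th, cur$len, cur$path)) {
        dests[[di]]$th <<- th_d; dests[[di]]$len <<- len_d
        dests[[di]]$path <<- path
      }
    }
    if (!mem[[midx[e]]]$full) return()
    exit_node <- if (entry == 0) net$links$node_b[e] else net$links$node_a[e]
    th_exit <- th_in + o_internal(geo[[e]], 0, L[e])
    len_exit <- len_in + L[e]
    g <- geo[[e]]; m <- nrow(g)
    av <- if (entry == 0) g[m, ] - g[m - 1, ] else g[1, ] - g[2, ]
    inc <- which(net$links$node_a == exit_node | net$links$node_b == exit_node)
    for (f in inc) {
      for (u in 0:1) {
        fnode <- if (u == 0) net$links$node_a[f] else net$links$node_b[f]
        if (fnode != exit_node) next
        if (f == e) next
        if (is.na(midx[f])) next
        Mf <- mem[[midx[f]]]
        ok <- any(if (u == 0) Mf$ivals[, 1] <= 1e-9 else Mf$ivals[, 2] >= L[f] - 1e-9)
        if (!ok) next
        sid <- paste0(f, ":", u)
        if (sid %in% visited) next
        gf <- geo[[f]]; mf <- nrow(gf)
        dv <- if (u == 0) gf[2, ] - gf[1, ] else gf[mf - 1, ] - gf[mf, ]
        visit(f, u, th_exit + o_angle(av, dv), len_exit, c(path, f),
              c(visited, sid))
      }
    }
  }
  go <- geo[[oi]]; mo <- nrow(go)
  for (side in 0:1) {
    l0 <- if (side == 0) s0 else L[oi] - s0
    if (continuous && l0 > r + 1e-9) next
    th0 <- if (side == 0) o_internal(go, 0, s0) else o_internal(go, s0, L[oi])
    node <- if (side == 0) net$links$node_a[oi] else net$links$node_b[oi]
    av <- if (side == 0) go[1, ] - go[2, ] else go[mo, ] - go[mo - 1, ]
    inc <- which(net$links$node_a == node | net$links$node_b == node)
    for (f in inc) {
      for (u in 0:1) {
        fnode <- if (u == 0) net$links$node_a[f] else net$links$node_b[f]
        if (fnode != node) next
        if (f == oi) next
        if (is.na(midx[f])) next
        Mf <- mem[[midx[f]]]
        ok <- any(if (u == 0) Mf$ivals[, 1] <= 1e-9 else Mf$ivals[, 2] >= L[f] - 1e-9)
        if (!ok) next
        gf <- geo[[f]]; mf <- nrow(gf)
        dv <- if (u == 0) gf[2, ] - gf[1, ] else gf[mf - 1, ] - gf[mf, ]
        visit(f, u, th0 + o_angle(av, dv), l0, c(oi, f), paste0(f, ":", u))
      }
    }
  }
  dests
}

# full 13 local metrics + destination table for one origin
oracle_metrics <- function(net, origin_id, r, continuous = TRUE, delta = 1) {
  oi <- match(origin_id, net$links$link_id)
  s0 <- net$links$length_m[oi] / 2
  sub <- oracle_subsystem(net, oi, s0, r, continuous)
  dests <- oracle_geodesics(net, sub)
  links <- sum(vapply(sub$members, `[[`, numeric(1), "P"))
  length_m <- sum(vapply(sub$members, `[[`, numeric(1), "included_len"))
  origin_pt <- sub$origin_pt
  nq <- 0; sP <- 0; sMG <- 0; sMC <- 0; sMA <- 0; sDiv <- 0; sPdiv <- 0
  dropped <- 0
  for (D in dests) {
    if (is.null(D$path)) { dropped <- dropped + 1; next }
    rp <- o_interp(net$links$geometry[[D$e]], D$rep)
    crow <- sqrt(sum((rp - origin_pt)^2))
    nq <- nq + D$P / max(D$th, delta)
    sP <- sP + D$P
    sMG <- sMG + D$P * D$len
    sMC <- sMC + D$P * crow
    sMA <- sMA + D$P * D$th
    if (crow > 1e-9) { sDiv <- sDiv + D$P * D$len / crow; sPdiv <- sPdiv + D$P }
  }
  deg <- net$nodes$degree
  jn <- which(deg >= 3 &
                unname(sub$d[paste0("N", net$nodes$node_id)]) <= r + 1e-9)
  hull <- oracle_hull(sub$reached, origin_pt)
  out <- c(links, length_m, nq,
           if (sP > 0) sMG / sP else NA, if (sP > 0) sMC / sP else NA,
           if (sP > 0) sMA / sP else NA,
           if (sPdiv > 0) sDiv / sPdiv else NA,
           length(jn), sum(deg[jn]), hull)
  names(out) <- c("Links", "Length", "NQPDA", "MGLA", "MCF", "MAD", "DivA",
                  "Jnc", "Con", "HullA", "HullP", "HullR", "HullSI")
  out
}

# betweenness family by explicit pairwise ledger over all origins
oracle_betweenness <- function(net, r, continuous = TRUE) {
  nL <- nrow(net$links)
  BtA <- TPBtA <- TPDA <- numeric(nL)
  ledger <- list()
  for (oi in seq_len(nL)) {
    s0 <- net$links$length_m[oi] / 2
    sub <- oracle_subsystem(net, oi, s0, r, continuous)
    dests <- oracle_geodesics(net, sub)
    W <- net$links$weight[oi]
    totP <- sum(vapply(sub$members, `[[`, numeric(1), "P"))
    if (totP <= 0) next
    Po <- sub$members[[1]]$P
    BtA[oi] <- BtA[oi] + W * Po / 3
    TPBtA[oi] <- TPBtA[oi] + W * (Po / totP) / 3
    TPDA[oi] <- TPDA[oi] + W * Po / totP
    ledger[[length(ledger) + 1]] <-
      data.frame(origin = oi, dest = oi, trips = W * Po / totP, sigma_sum = 1 / 3)
    for (D in dests) {
      TPDA[D$e] <- TPDA[D$e] + W * D$P / totP
      if (is.null(D$path)) next
      path <- D$path
      sig <- rep(1, length(path))
      sig[1] <- 0.5; sig[length(path)] <- 0.5
      for (j in seq_along(path)) {
        BtA[path[j]] <- BtA[path[j]] + W * D$P * sig[j]
        TPBtA[path[j]] <- TPBtA[path[j]] + W * (D$P / totP) * sig[j]
      }
      ledger[[length(ledger) + 1]] <-
        data.frame(origin = oi, dest = D$e, trips = W * D$P / totP,
                   sigma_sum = sum(sig))
    }
  }
  list(BtA = BtA, TPBtA = TPBtA, TPDA = TPDA,
       ledger = do.call(rbind, ledger))
}
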