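test_that("geodesic distances match closed-form haversine values", {
  expect_equal(geodesic_km(0, 0, 0, 0), 0)
  expect_equal(geodesic_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-6)
  expect_equal(geodesic_km(0, 0, 0, 1), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-6)
  # vectorized
  expect_length(geodesic_km(c(0, 10), c(0, 0), 0, 1), 2)
  expect_error(geodesic_km(95, 0, 0, 0))
})

test_that("raster graphs have lattice topology and latitude-corrected steps", {
  g9 <- fixture_graph(3, 3)
  deg <- igraph::degree(g9$g)
  expect_equal(deg[node_at(g9, 2, 2)], 8)        # interior node, 8-connected

  strip <- build_graph(0, seq(0, 2, 0.5))        # 1 x 5 strip
  expect_equal(nrow(strip$edges), 4)
  expect_equal(igraph::degree(strip$g)[c(1, 5)], c(1, 1),
               ignore_attr = TRUE)

  # an E-W step at 60N is about half the equatorial E-W step
  eq <- geodesic_km(0, 0, 0, 0.5)
  north <- geodesic_km(60, 0, 60, 0.5)
  expect_equal(north / eq, cos(60 * pi / 180), tolerance = 1e-3)

  g16 <- build_graph(c(0, 0.5, 1), c(0, 0.5, 1), connectivity = 16)
  expect_gt(nrow(g16$edges), nrow(g9$edges))
  expect_error(build_graph(0, 0), "2 land cells")
})

test_that("a constant surface gives zero cost and a minimum-length path", {
  g <- fixture_graph(6, 6)
  env <- matrix(5, 6, 6)
  start <- node_at(g, 1, 1); end <- node_at(g, 6, 6)
  p <- env_cost_path(g, env, start, end)
  expect_equal(p$accumulated_cost, 0)
  # 8-connectivity: the diagonal chain is the minimum-length lattice path
  diag_len <- sum(geodesic_km((0:4) * 0.5, (0:4) * 0.5,
                              (1:5) * 0.5, (1:5) * 0.5))
  expect_equal(p$length_km, diag_len, tolerance = 1e-9)
  expect_gte(p$length_km, geodesic_km(g$nodes$lat[start], g$nodes$lon[start],
                                      g$nodes$lat[end], g$nodes$lon[end]))
})

test_that("environmental and topographic paths match the brute-force oracle on random grids", {
  set.seed(2024)
  for (rep in 1:12) {
    nr <- sample(8:15, 1); nc <- sample(8:15, 1)
    g <- fixture_graph(nr, nc, lat0 = runif(1, -40, 40))
    env <- matrix(rnorm(nr * nc, 0, 2), nr, nc)
    elev <- matrix(rnorm(nr * nc, 0, 800), nr, nc)
    ends <- sample(nrow(g$nodes), 2)
    p_env <- env_cost_path(g, env, ends[1], ends[2])
    w_env <- env_edge_weights(g, grid_at_nodes_test(g, env), ends[1])
    oracle_env <- bf_shortest(nrow(g$nodes), g$edges$from, g$edges$to,
                              w_env, ends[1], ends[2])
    expect_equal(p_env$accumulated_cost + 1e-9 * p_env$length_km,
                 oracle_env, tolerance = 1e-9)

    p_topo <- topo_cost_path(g, elev, ends[1], ends[2])
    w_topo <- topo_edge_weights(g, grid_at_nodes_test(g, elev))
    oracle_topo <- bf_shortest(nrow(g$nodes), g$edges$from, g$edges$to,
                               w_topo, ends[1], ends[2])
    expect_equal(p_topo$accumulated_cost, oracle_topo, tolerance = 1e-9)
  }
})

test_that("paths route through a zero-cost gap in a high-cost wall", {
  # 7x7 grid, env = 0 everywhere except a vertical wall at col 4 with value
  # 10, pierced by a zero gap at row 4
  g <- fixture_graph(7, 7)
  env <- matrix(0, 7, 7)
  env[, 4] <- 10
  env[4, 4] <- 0
  p <- env_cost_path(g, env, node_at(g, 1, 1), node_at(g, 7, 7))
  cols <- g$nodes$col[p$path]
  rows <- g$nodes$row[p$path]
  expect_equal(rows[cols == 4], 4)               # crosses only at the gap
  expect_equal(p$accumulated_cost, 0, tolerance = 1e-12)
})

test_that("a flat detour beats a steep ridge when its total weight is lower", {
  # 3-row corridor: direct route over a huge ridge vs a flat detour row
  g <- fixture_graph(3, 5)
  elev <- matrix(0, 3, 5)
  elev[2, 3] <- 8e5                               # absurdly steep ridge cell
  elev[1, 3] <- 8e5                               # block the top row too
  start <- node_at(g, 2, 1); end <- node_at(g, 2, 5)
  p <- topo_cost_path(g, elev, start, end)
  expect_true(all(g$nodes$row[p$path] %in% c(2, 3)))
  expect_false(any(p$path %in% c(node_at(g, 2, 3), node_at(g, 1, 3))))
  # flat terrain limit: cost equals length
  p0 <- topo_cost_path(g, matrix(0, 3, 5), start, end)
  expect_equal(p0$accumulated_cost, p0$length_km, tolerance = 1e-12)
})

test_that("accumulated cost scales linearly with the surface", {
  g <- fixture_graph(8, 8)
  set.seed(5)
  env <- matrix(rexp(64), 8, 8)
  s <- node_at(g, 1, 2); e <- node_at(g, 8, 7)
  p1 <- env_cost_path(g, env, s, e)
  p3 <- env_cost_path(g, env * 3, s, e)
  expect_equal(p3$accumulated_cost, 3 * p1$accumulated_cost,
               tolerance = 1e-9)
})

test_that("disconnected endpoints are flagged, not silently mis-scored", {
  mask <- matrix(TRUE, 3, 5)
  mask[, 3] <- FALSE                              # ocean column splits halves
  g <- build_graph(c(0, 0.5, 1), seq(0, 2, 0.5), mask = mask)
  p <- env_cost_path(g, matrix(1, 3, 5), node_at(g, 1, 1), node_at(g, 1, 5))
  expect_false(p$reachable)
  expect_true(is.na(p$accumulated_cost))
})

test_that("pair_barriers is symmetric, zero on identical cells and bounded by geodesics", {
  cfg <- tiny_config(n_societies = 25)
  w <- suppressMessages(simulate_world(cfg, n_traits = 1))
  pairs <- nearest_pairs(w$societies, k = 6)
  b <- suppressMessages(pair_barriers(pairs, w$societies, w$env,
                                      w$elevation, w$graph,
                                      log_transform = FALSE))
  # argument swap gives the identical record
  swapped <- pairs[, c("id_B", "id_A")]
  names(swapped) <- c("id_A", "id_B")
  b2 <- suppressMessages(pair_barriers(swapped, w$societies, w$env,
                                       w$elevation, w$graph,
                                       log_transform = FALSE))
  num <- c("geodesic_km", "th_dissim", "ai_dissim", "th_cost", "th_len",
           "ai_cost", "ai_len", "topo_cost", "topo_len")
  for (cc in num) expect_equal(b[[cc]], b2[[cc]], tolerance = 1e-10)

  # path length at least the geodesic (snapped-cell geometry can differ from
  # the society coordinates by at most one cell, so compare on node centers)
  ok <- !b$excluded
  expect_true(all(b$th_len[ok] + 1e-6 >=
                    geodesic_km(w$societies$lat[match(b$id_A[ok], w$societies$id)],
                                w$societies$lon[match(b$id_A[ok], w$societies$id)],
                                w$societies$lat[match(b$id_B[ok], w$societies$id)],
                                w$societies$lon[match(b$id_B[ok], w$societies$id)])))

  # same-cell pair: all costs and lengths zero
  soc2 <- tibble::tibble(id = c("x1", "x2"),
                         lat = w$societies$lat[1], lon = w$societies$lon[1])
  b0 <- suppressMessages(pair_barriers(
    tibble::tibble(id_A = "x1", id_B = "x2"), soc2, w$env, w$elevation,
    w$graph, log_transform = FALSE))
  expect_equal(unlist(b0[, num]), setNames(rep(0, length(num)), num))

  # constant TH surface: th_cost identically zero regardless of AI structure
  envc <- list(th = matrix(0, cfg$grid_n_lat, cfg$grid_n_lon),
               ai = axes_to_grid(w$env, "AI"))
  bc <- suppressMessages(pair_barriers(pairs, w$societies, envc,
                                       w$elevation, w$graph,
                                       log_transform = FALSE))
  expect_true(all(bc$th_cost[!bc$excluded] == 0))
  expect_true(any(bc$ai_cost[!bc$excluded] > 0))
})

test_that("directional env paths differ before symmetrization", {
  g <- fixture_graph(9, 9)
  set.seed(3)
  env <- matrix(rnorm(81, 0, 3), 9, 9)
  a <- node_at(g, 2, 2); b <- node_at(g, 8, 8)
  ab <- env_cost_path(g, env, a, b)
  ba <- env_cost_path(g, env, b, a)
  expect_false(isTRUE(all.equal(ab$accumulated_cost, ba$accumulated_cost)))
})
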