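# Shared fixtures and independent oracles for the test suite.

# Small world configuration used across tests (kept tiny for speed).
tiny_config <- function(...) {
  defaults <- list(grid_n_lat = 12, grid_n_lon = 16, lat_range = c(-55, 55),
                   lon_range = c(0, 40), years = 12, n_societies = 30,
                   seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(world_config, args)
}

# Independent brute-force shortest path: Bellman-Ford edge relaxation over
# an explicit weighted edge list (both directions). Returns the minimal
# total weight from `start` to `end`, Inf if unreachable.
bf_shortest <- function(n_nodes, from, to, w, start, end) {
  f2 <- c(from, to); t2 <- c(to, from); w2 <- c(w, w)
  dist <- rep(Inf, n_nodes)
  dist[start] <- 0
  for (iter in seq_len(n_nodes)) {
    cand <- dist[f2] + w2
    m <- tapply(cand, t2, min)            # best incoming offer per node
    idx <- as.integer(names(m))
    newd <- dist
    newd[idx] <- pmin(newd[idx], m)
    if (identical(newd, dist)) break
    dist <- newd
  }
  dist[end]
}

# env-path edge weights exactly as specified: step * mean endpoint cost
# plus the eps * step tie-breaker, with cost relative to the start cell.
env_edge_weights <- function(graph, env_node, start, eps = 1e-9) {
  cc <- abs(env_node - env_node[start])
  graph$edges$step_km * (cc[graph$edges$from] + cc[graph$edges$to]) / 2 +
    eps * graph$edges$step_km
}

grid_at_nodes_test <- function(graph, m) {
  m[cbind(graph$nodes$row, graph$nodes$col)]
}

topo_edge_weights <- function(graph, elev_node) {
  slope <- abs(elev_node[graph$edges$from] - elev_node[graph$edges$to]) /
    (graph$edges$step_km * 1000)
  graph$edges$step_km * (1 + slope)
}

# Independent Colwell predictability oracle: direct entropy computation on
# the month-by-state contingency table, written without reusing package
# internals.
colwell_oracle <- function(states, n_states) {
  month <- rep_len(1:12, length(states))
  tab <- matrix(0, 12, n_states)
  for (i in seq_along(states)) tab[month[i], states[i]] <- tab[month[i], states[i]] + 1
  Z <- sum(tab)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  HX <- H(rowSums(tab) / Z); HY <- H(colSums(tab) / Z); HXY <- H(tab / Z)
  1 - (HXY - HX) / log(n_states)
}

# A flat-lat/lon grid graph on a small matrix for fixture paths.
fixture_graph <- function(nr, nc, lat0 = 0, step_deg = 0.5) {
  lat <- lat0 + (seq_len(nr) - 1) * step_deg
  lon <- (seq_len(nc) - 1) * step_deg
  build_graph(lat, lon)
}

node_at <- function(graph, row, col) {
  graph$nodes$node[graph$nodes$row == row & graph$nodes$col == col]
}

# Random-intercept Bernoulli pair data simulated from the fitted model
# itself (used for recovery and calibration checks).
simulate_pair_model <- function(n_pairs, n_soc, beta, sigma = 0.7,
                                intercept = 0) {
  ids <- sprintf("s%03d", seq_len(n_soc))
  id_A <- sample(ids, n_pairs, replace = TRUE)
  id_B <- vapply(id_A, function(a) sample(setdiff(ids, a), 1), character(1))
  X <- matrix(rnorm(n_pairs * length(beta)), n_pairs)
  colnames(X) <- paste0("x", seq_along(beta))
  u <- setNames(rnorm(n_soc, 0, sigma), ids)
  eta <- intercept + as.numeric(X %*% beta) + u[id_A] + u[id_B]
  dplyr::bind_cols(
    tibble::tibble(id_A = id_A, id_B = id_B,
                   share = rbinom(n_pairs, 1, plogis(eta))),
    tibble::as_tibble(X))
}
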