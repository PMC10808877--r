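#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km. Vectorized
#' over the coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS 84).
#' @return Distance(s) in km.
#' @examples
#' geodesic_km(0, 0, 0, 1)  # ~111.19 km
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
}

#' Build the geographically corrected raster graph
#'
#' Land cells become nodes; neighbouring cells (8-connected by default,
#' 16-connected adds knight moves) are linked by edges carrying the
#' great-circle distance between cell centers, so east-west steps shrink
#' with latitude as they do on the globe.
#'
#' @param lat,lon Cell-center coordinate vectors (rows x cols grid).
#' @param mask Optional logical matrix (`TRUE` = land); default all-land.
#' @param connectivity 8 or 16.
#' @return An object of class `raster_graph`: list with `nodes` (tibble
#'   `node`, `row`, `col`, `lat`, `lon`), `edges` (tibble `from`, `to`,
#'   `step_km`), the `igraph` object `g`, and `dims`.
#' @export
build_graph <- function(lat, lon, mask = NULL, connectivity = 8) {
  nr <- length(lat); nc <- length(lon)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  stopifnot(all(dim(mask) == c(nr, nc)), connectivity %in% c(8, 16))
  land <- which(mask)
  if (length(land) < 2) abort("at least 2 land cells are required")
  node_of_cell <- rep(NA_integer_, nr * nc)
  node_of_cell[land] <- seq_along(land)
  rc <- arrayInd(land, c(nr, nc))
  nodes <- tibble::tibble(node = seq_along(land),
                          row = rc[, 1], col = rc[, 2],
                          lat = lat[rc[, 1]], lon = lon[rc[, 2]])
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  if (connectivity == 16) {
    offs <- rbind(offs, c(1, 2), c(2, 1), c(2, -1), c(1, -2))
  }
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- nodes$row + offs[k, 1]; c2 <- nodes$col + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    tgt <- rep(NA_integer_, nrow(nodes))
    tgt[ok] <- node_of_cell[(c2[ok] - 1L) * nr + r2[ok]]
    keep <- ok & !is.na(tgt)
    from <- c(from, nodes$node[keep]); to <- c(to, tgt[keep])
  }
  step_km <- geodesic_km(nodes$lat[from], nodes$lon[from],
                         nodes$lat[to], nodes$lon[to])
  edges <- tibble::tibble(from = from, to = to, step_km = step_km)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < nrow(nodes)) {
    g <- igraph::add_vertices(g, nrow(nodes) - igraph::vcount(g))
  }
  structure(list(nodes = nodes, edges = edges, g = g, dims = c(nr, nc),
                 node_of_cell = node_of_cell),
            class = "raster_graph")
}

#' @export
print.raster_graph <- function(x, ...) {
  cat("<raster_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges on a ", x$dims[1], "x", x$dims[2], " grid\n", sep = "")
  invisible(x)
}

#' Snap coordinates to graph nodes
#'
#' Maps each coordinate to its containing grid cell; coordinates landing on
#' a masked (non-land) cell are snapped to the nearest land node within a
#' 2-cell window, otherwise an error is raised.
#'
#' @param graph A [build_graph()] object.
#' @param lat,lon Coordinate vectors.
#' @param max_cells Search window (cells) for masked coordinates.
#' @return Integer node ids.
#' @export
snap_to_cell <- function(graph, lat, lon, max_cells = 2) {
  lats <- sort(unique(graph$nodes$lat))
  latr <- vapply(lat, function(x) which.min(abs(lats - x)), integer(1))
  lons <- sort(unique(graph$nodes$lon))
  # recover full grid axes from dims: rows/cols may be partially masked, so
  # rebuild from the node table which carries row/col plus lat/lon
  row_lat <- tapply(graph$nodes$lat, graph$nodes$row, unique)
  col_lon <- tapply(graph$nodes$lon, graph$nodes$col, unique)
  rows <- as.integer(names(row_lat)); cols <- as.integer(names(col_lon))
  vapply(seq_along(lat), function(i) {
    r <- rows[which.min(abs(unlist(row_lat) - lat[i]))]
    cc <- cols[which.min(abs(unlist(col_lon) - lon[i]))]
    hit <- graph$nodes$node[graph$nodes$row == r & graph$nodes$col == cc]
    if (length(hit) == 1) return(hit)
    cand <- graph$nodes[abs(graph$nodes$row - r) <= max_cells &
                          abs(graph$nodes$col - cc) <= max_cells, ]
    if (nrow(cand) == 0) {
      abort(sprintf("no land cell within %d cells of (%.2f, %.2f)",
                    max_cells, lat[i], lon[i]))
    }
    d <- geodesic_km(lat[i], lon[i], cand$lat, cand$lon)
    cand$node[which.min(d)]
  }, integer(1))
}

# per-node value vector from a grid matrix
grid_at_nodes <- function(graph, m) {
  m[cbind(graph$nodes$row, graph$nodes$col)]
}

# Core one-to-many least-cost computation. `cell_cost` is the per-node cost
# c(v) >= 0; edge weight = step * (c(u) + c(v)) / 2 + eps * step. Returns a
# tibble (end, cost, len) with NA for unreachable ends; cost excludes eps.
lcp_from <- function(graph, cell_cost, start, ends, eps = 1e-9,
                     keep_paths = FALSE) {
  cmean <- (cell_cost[graph$edges$from] + cell_cost[graph$edges$to]) / 2
  w <- graph$edges$step_km * cmean + eps * graph$edges$step_km
  sp <- suppressWarnings(
    igraph::shortest_paths(graph$g, from = start, to = unique(ends),
                           weights = w, output = "vpath"))
  got <- setNames(sp$vpath, as.character(unique(ends)))
  res <- purrr::map(as.character(ends), function(e) {
    v <- as.integer(got[[e]])
    if (length(v) == 0) {
      return(list(cost = NA_real_, len = NA_real_, path = integer(0)))
    }
    if (length(v) == 1) return(list(cost = 0, len = 0, path = v))
    steps <- geodesic_km(graph$nodes$lat[v[-length(v)]],
                         graph$nodes$lon[v[-length(v)]],
                         graph$nodes$lat[v[-1]], graph$nodes$lon[v[-1]])
    cc <- (cell_cost[v[-length(v)]] + cell_cost[v[-1]]) / 2
    list(cost = sum(steps * cc), len = sum(steps), path = v)
  })
  out <- tibble::tibble(
    end = as.integer(ends),
    cost = vapply(res, `[[`, numeric(1), "cost"),
    len = vapply(res, `[[`, numeric(1), "len"))
  if (keep_paths) out$path <- purrr::map(res, "path")
  out
}

#' Start-relative environmental least-cost path
#'
#' The cost of traversing a cell is its absolute environmental difference
#' from the *starting* cell, so the surface (and hence the path) differs
#' between the two directions of a pair. Edge weight is the step length
#' times the mean endpoint cost, plus a tiny `eps * step` tie-breaker that
#' steers zero-cost surfaces toward shortest paths. The reported
#' accumulated cost excludes the tie-breaker.
#'
#' @param graph A [build_graph()] object.
#' @param env_grid Matrix of environmental scores on the grid (e.g. TH).
#' @param start,end Node ids (see [snap_to_cell()]).
#' @param eps Tie-breaking weight per km.
#' @return A list of class `path_result`: `accumulated_cost`, `length_km`,
#'   `path` (node sequence; empty if unreachable), `reachable`.
#' @export
env_cost_path <- function(graph, env_grid, start, end, eps = 1e-9) {
  env_node <- grid_at_nodes(graph, env_grid)
  if (any(!is.finite(env_node))) abort("env_grid not finite on land cells")
  cost <- abs(env_node - env_node[start])
  r <- lcp_from(graph, cost, start, end, eps = eps, keep_paths = TRUE)
  structure(list(accumulated_cost = r$cost[1], length_km = r$len[1],
                 path = r$path[[1]], reachable = !is.na(r$cost[1])),
            class = "path_result")
}

#' Slope-based topographic least-cost path
#'
#' Edge weight is `step_km * (1 + |rise| / run)` with the rise in metres and
#' the run in metres, i.e. length inflated by the slope magnitude. The
#' weight is symmetric, so A->B and B->A agree. The accumulated cost is the
#' minimized total weight; on flat terrain it equals the path length.
#'
#' @param graph A [build_graph()] object.
#' @param elev_grid Elevation matrix (m).
#' @param start,end Node ids.
#' @return A `path_result` as in [env_cost_path()].
#' @export
topo_cost_path <- function(graph, elev_grid, start, end) {
  r <- topo_from(graph, elev_grid, start, end, keep_paths = TRUE)
  structure(list(accumulated_cost = r$cost[1], length_km = r$len[1],
                 path = r$path[[1]], reachable = !is.na(r$cost[1])),
            class = "path_result")
}

topo_from <- function(graph, elev_grid, start, ends, keep_paths = FALSE) {
  elev <- grid_at_nodes(graph, elev_grid)
  if (any(!is.finite(elev))) abort("elev_grid not finite on land cells")
  slope <- abs(elev[graph$edges$from] - elev[graph$edges$to]) /
    (graph$edges$step_km * 1000)
  w <- graph$edges$step_km * (1 + slope)
  sp <- suppressWarnings(
    igraph::shortest_paths(graph$g, from = start, to = unique(ends),
                           weights = w, output = "vpath"))
  got <- setNames(sp$vpath, as.character(unique(ends)))
  res <- purrr::map(as.character(ends), function(e) {
    v <- as.integer(got[[e]])
    if (length(v) == 0) {
      return(list(cost = NA_real_, len = NA_real_, path = integer(0)))
    }
    if (length(v) == 1) return(list(cost = 0, len = 0, path = v))
    steps <- geodesic_km(graph$nodes$lat[v[-length(v)]],
                         graph$nodes$lon[v[-length(v)]],
                         graph$nodes$lat[v[-1]], graph$nodes$lon[v[-1]])
    sl <- abs(elev[v[-length(v)]] - elev[v[-1]]) / (steps * 1000)
    list(cost = sum(steps * (1 + sl)), len = sum(steps), path = v)
  })
  out <- tibble::tibble(
    end = as.integer(ends),
    cost = vapply(res, `[[`, numeric(1), "cost"),
    len = vapply(res, `[[`, numeric(1), "len"))
  if (keep_paths) out$path <- purrr::map(res, "path")
  out
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$reachable) {
    cat("<path_result> unreachable\n")
  } else {
    cat("<path_result> cost ", signif(x$accumulated_cost, 5), ", length ",
        signif(x$length_km, 5), " km, ", length(x$path), " nodes\n", sep = "")
  }
  invisible(x)
}

#' Pairwise barrier metrics
#'
#' For every pair, computes the 9 path/dissimilarity barriers plus geodesic
#' distance: local `|dTH|` and `|dAI|`; mean accumulated cost and mean
#' length of the two directional start-relative TH paths and AI paths;
#' topographic path cost and length (symmetric weights, computed once).
#' Cost and length fields are `log(1 + x)`-transformed when
#' `log_transform = TRUE` (the default used by the sharing models).
#' Disconnected pairs are returned with `excluded = TRUE` and a reason.
#'
#' The record is symmetric in the pair by construction: directional env
#' paths are averaged and all other ingredients are symmetric.
#'
#' @param pairs Tibble with `id_A`, `id_B` (e.g. from [nearest_pairs()]).
#' @param societies Society tibble (`id`, `lat`, `lon`).
#' @param env An `env_axes` object (or list with `TH`/`AI` grid matrices as
#'   `th`, `ai`).
#' @param elev_grid Elevation matrix (m).
#' @param graph A [build_graph()] object.
#' @param eps Tie-breaking weight for the env paths.
#' @param log_transform Apply `log1p` to cost/length fields.
#' @return A tibble keyed by (`id_A`, `id_B`) with columns `geodesic_km`,
#'   `th_dissim`, `ai_dissim`, `th_cost`, `th_len`, `ai_cost`, `ai_len`,
#'   `topo_cost`, `topo_len`, `excluded`, `reason`.
#' @export
pair_barriers <- function(pairs, societies, env, elev_grid, graph,
                          eps = 1e-9, log_transform = TRUE) {
  th_m <- if (inherits(env, "env_axes")) axes_to_grid(env, "TH") else env$th
  ai_m <- if (inherits(env, "env_axes")) axes_to_grid(env, "AI") else env$ai
  soc <- societies
  soc$node <- snap_to_cell(graph, soc$lat, soc$lon)
  node_of <- setNames(soc$node, soc$id)
  pairs <- dplyr::mutate(pairs,
                         node_A = node_of[.data$id_A],
                         node_B = node_of[.data$id_B])
  th_node <- grid_at_nodes(graph, th_m)
  ai_node <- grid_at_nodes(graph, ai_m)

  # directed env paths grouped by start node (one Dijkstra per surface/start)
  directed <- dplyr::bind_rows(
    dplyr::transmute(pairs, start = .data$node_A, end = .data$node_B),
    dplyr::transmute(pairs, start = .data$node_B, end = .data$node_A))
  directed <- dplyr::distinct(directed)
  env_dir <- directed %>%
    dplyr::group_by(.data$start) %>%
    dplyr::group_modify(function(d, key) {
      s <- key$start
      th <- lcp_from(graph, abs(th_node - th_node[s]), s, d$end, eps = eps)
      ai <- lcp_from(graph, abs(ai_node - ai_node[s]), s, d$end, eps = eps)
      tibble::tibble(end = d$end,
                     th_cost = th$cost, th_len = th$len,
                     ai_cost = ai$cost, ai_len = ai$len)
    }) %>%
    dplyr::ungroup()

  lookup <- function(s, e, col) {
    i <- match(paste(s, e), paste(env_dir$start, env_dir$end))
    env_dir[[col]][i]
  }
  res <- pairs %>%
    dplyr::mutate(
      geodesic_km = geodesic_km(
        soc$lat[match(.data$id_A, soc$id)], soc$lon[match(.data$id_A, soc$id)],
        soc$lat[match(.data$id_B, soc$id)], soc$lon[match(.data$id_B, soc$id)]),
      th_dissim = abs(th_node[.data$node_A] - th_node[.data$node_B]),
      ai_dissim = abs(ai_node[.data$node_A] - ai_node[.data$node_B]),
      th_cost = (lookup(.data$node_A, .data$node_B, "th_cost") +
                   lookup(.data$node_B, .data$node_A, "th_cost")) / 2,
      th_len = (lookup(.data$node_A, .data$node_B, "th_len") +
                  lookup(.data$node_B, .data$node_A, "th_len")) / 2,
      ai_cost = (lookup(.data$node_A, .data$node_B, "ai_cost") +
                   lookup(.data$node_B, .data$node_A, "ai_cost")) / 2,
      ai_len = (lookup(.data$node_A, .data$node_B, "ai_len") +
                  lookup(.data$node_B, .data$node_A, "ai_len")) / 2)

  # topographic paths: symmetric weights, one run per distinct start
  topo_dir <- pairs %>%
    dplyr::distinct(.data$node_A, .data$node_B) %>%
    dplyr::group_by(.data$node_A) %>%
    dplyr::group_modify(function(d, key) {
      r <- topo_from(graph, elev_grid, key$node_A, d$node_B)
      tibble::tibble(node_B = d$node_B, topo_cost = r$cost, topo_len = r$len)
    }) %>%
    dplyr::ungroup()
  res <- dplyr::left_join(res, topo_dir, by = c("node_A", "node_B"))

  res <- res %>%
    dplyr::mutate(
      excluded = !is.finite(.data$th_cost) | !is.finite(.data$topo_cost),
      reason = dplyr::if_else(.data$excluded, "disconnected", NA_character_))
  if (log_transform) {
    for (cl in c("th_cost", "th_len", "ai_cost", "ai_len",
                 "topo_cost", "topo_len")) {
      res[[cl]] <- log1p(res[[cl]])
    }
  }
  n_ex <- sum(res$excluded)
  if (n_ex > 0) inform(sprintf("pair_barriers: %d disconnected pairs excluded", n_ex))
  dplyr::select(res, -"node_A", -"node_B")
}
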