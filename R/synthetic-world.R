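#' Grid geometry helpers
#'
#' Cell centers of the regular lat/lon grid described by a `world_config`.
#' Rows run south to north, columns west to east.
#'
#' @param config A [world_config()].
#' @return A list with numeric vectors `lat` (length `grid_n_lat`) and
#'   `lon` (length `grid_n_lon`).
#' @export
grid_centers <- function(config) {
  lat_step <- diff(config$lat_range) / config$grid_n_lat
  lon_step <- diff(config$lon_range) / config$grid_n_lon
  list(
    lat = config$lat_range[1] + (seq_len(config$grid_n_lat) - 0.5) * lat_step,
    lon = config$lon_range[1] + (seq_len(config$grid_n_lon) - 0.5) * lon_step
  )
}

#' Generate a monthly climate series on the world grid
#'
#' Temperature at a cell is a latitude-dependent annual mean plus a seasonal
#' sinusoid whose amplitude grows linearly with `|lat|` (phase flipped across
#' the equator) plus Gaussian white noise. Precipitation follows a
#' latitudinal wet-belt profile (wet equator, drier subtropics, moderately
#' wet mid-latitudes) with a seasonal component and truncated Gaussian
#' noise, so it is non-negative everywhere.
#'
#' @param config A [world_config()].
#' @return An object of class `climate_stack`: a list with `temp` and
#'   `precip` arrays of dimension `grid_n_lat x grid_n_lon x (12 * years)`
#'   plus the `lat`/`lon` cell-center vectors.
#' @examples
#' cl <- generate_climate(world_config(years = 2, seed = 3))
#' dim(cl$temp)
#' @export
generate_climate <- function(config) {
  validate_world_config(config)
  if (config$grid_n_lat * config$grid_n_lon < 2) {
    abort("degenerate grid: at least two cells are required")
  }
  g <- grid_centers(config)
  n_month <- 12L * config$years
  month_of_year <- ((seq_len(n_month) - 1L) %% 12L) + 1L
  season <- sin(2 * pi * (month_of_year - 1) / 12)
  max_abs_lat <- max(abs(g$lat))
  amp_lat <- config$seasonality_amp * abs(g$lat) / max(max_abs_lat, 1e-12)

  mean_t <- 25 - 0.45 * abs(g$lat)                       # deg C by latitude
  wet <- config$precip_base *
    (0.25 + 1.5 * exp(-(g$lat / 20)^2) + 0.5 * exp(-((abs(g$lat) - 50) / 12)^2))

  dims <- c(config$grid_n_lat, config$grid_n_lon, n_month)
  temp <- array(0, dims)
  precip <- array(0, dims)
  with_stage_seed(stage_seed(config$seed, "climate"), {
    for (m in seq_len(n_month)) {
      t_det <- mean_t + sign(g$lat) * amp_lat * season[m]
      p_det <- wet * (1 + 0.3 * sin(2 * pi * (month_of_year[m] - 1) / 12 + pi / 3))
      temp[, , m] <- matrix(t_det, dims[1], dims[2]) +
        if (config$noise_sd_temp > 0) {
          matrix(rnorm(dims[1] * dims[2], 0, config$noise_sd_temp), dims[1], dims[2])
        } else 0
      precip[, , m] <- pmax(
        matrix(p_det, dims[1], dims[2]) +
          if (config$noise_sd_precip > 0) {
            matrix(rnorm(dims[1] * dims[2], 0, config$noise_sd_precip), dims[1], dims[2])
          } else 0,
        0)
    }
  })
  structure(list(temp = temp, precip = precip, lat = g$lat, lon = g$lon),
            class = "climate_stack")
}

#' Generate a smooth elevation field
#'
#' Gaussian white noise low-pass filtered with a separable Gaussian kernel
#' (reflecting boundaries) and rescaled so the field's standard deviation is
#' `elevation_scale` metres. `elevation_scale = 0` returns a flat (all-zero)
#' grid.
#'
#' @param config A [world_config()].
#' @param smooth_sd Kernel standard deviation in cells.
#' @return Matrix `grid_n_lat x grid_n_lon` of elevations (m) with `lat`/`lon`
#'   attributes.
#' @export
generate_elevation <- function(config, smooth_sd = 2) {
  validate_world_config(config)
  g <- grid_centers(config)
  nr <- config$grid_n_lat; nc <- config$grid_n_lon
  if (config$elevation_scale == 0) {
    z <- matrix(0, nr, nc)
  } else {
    z <- with_stage_seed(stage_seed(config$seed, "elevation"), {
      matrix(rnorm(nr * nc), nr, nc)
    })
    z <- gauss_smooth(z, smooth_sd)
    z <- z - mean(z)
    s <- sd(as.vector(z))
    if (s > 0) z <- z * (config$elevation_scale / s)
  }
  attr(z, "lat") <- g$lat
  attr(z, "lon") <- g$lon
  z
}

# separable Gaussian convolution with reflecting edges
gauss_smooth <- function(z, smooth_sd) {
  half <- max(1L, ceiling(3 * smooth_sd))
  k <- exp(-(( -half:half)^2) / (2 * smooth_sd^2))
  k <- k / sum(k)
  smooth_vec <- function(v) {
    padded <- c(rev(v[seq_len(half)]), v, rev(v[(length(v) - half + 1):length(v)]))
    as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + length(v))]
  }
  z1 <- apply(z, 2, smooth_vec)
  t(apply(z1, 1, smooth_vec))
}

#' Place societies at land-cell centers
#'
#' Samples `n_societies` distinct land cells (all cells are land by default;
#' supply `mask` to restrict) and places one society at each cell center.
#'
#' @param config A [world_config()].
#' @param mask Optional logical matrix (`TRUE` = land) matching the grid.
#' @return A tibble with columns `id`, `lat`, `lon`, `origin_area`
#'   (all `NA`; see [assign_origin_areas()]).
#' @export
place_societies <- function(config, mask = NULL) {
  validate_world_config(config)
  g <- grid_centers(config)
  nr <- config$grid_n_lat; nc <- config$grid_n_lon
  land <- which(if (is.null(mask)) matrix(TRUE, nr, nc) else mask)
  if (config$n_societies > length(land)) {
    abort("more societies requested than land cells available")
  }
  cells <- with_stage_seed(stage_seed(config$seed, "societies"),
                           sample(land, config$n_societies))
  rc <- arrayInd(cells, c(nr, nc))
  tibble::tibble(
    id = sprintf("soc%03d", seq_len(config$n_societies)),
    lat = g$lat[rc[, 1]],
    lon = g$lon[rc[, 2]],
    origin_area = NA_character_
  )
}

#' Label societies with origin areas around fixed centers
#'
#' Assigns each society to the first listed area whose center lies within
#' `radius_km` (great-circle); societies outside every area keep `NA`. Each
#' society belongs to at most one area.
#'
#' @param societies Society tibble (`id`, `lat`, `lon`, ...).
#' @param centers Tibble/data frame with `area`, `lat`, `lon`.
#' @param radius_km Assignment radius in km.
#' @return `societies` with `origin_area` filled in.
#' @export
assign_origin_areas <- function(societies, centers, radius_km = 1200) {
  lab <- rep(NA_character_, nrow(societies))
  for (i in seq_len(nrow(centers))) {
    d <- geodesic_km(societies$lat, societies$lon,
                     centers$lat[i], centers$lon[i])
    lab[is.na(lab) & d <= radius_km] <- as.character(centers$area[i])
  }
  dplyr::mutate(societies, origin_area = lab)
}

#' Simulate an ultrametric Yule tree over the societies
#'
#' Pure-birth (Yule) tree with one tip per society, rescaled to unit
#' root-to-tip depth so branch lengths are comparable across worlds.
#'
#' @param n_societies Number of tips; tip labels are `soc001`, `soc002`, ...
#' @param seed Optional integer seed (omit to use the current RNG state).
#' @param birth Speciation rate of the pure-birth process.
#' @return An [ape::rphylo()] ultrametric `phylo` object.
#' @examples
#' tr <- simulate_tree(5, seed = 2)
#' ape::is.ultrametric(tr)
#' @export
simulate_tree <- function(n_societies, seed = NULL, birth = 1) {
  gen <- function() {
    tr <- ape::rphylo(n_societies, birth = birth, death = 0)
    tr$tip.label <- sprintf("soc%03d", seq_len(n_societies))
    depth <- max(ape::node.depth.edgelength(tr))
    if (depth > 0) tr$edge.length <- tr$edge.length / depth
    tr
  }
  if (is.null(seed)) gen() else with_stage_seed(seed, gen())
}

#' Evolve discrete traits along the tree, then a horizontal copying pass
#'
#' Vertical phase: the root draws a code uniformly from
#' `1:n_trait_categories`; along each branch of length `b` the code switches
#' with probability `1 - exp(-mu_vertical * b)` to a uniformly drawn
#' different code. Horizontal phase: societies are visited once in random
#' order; each draws one candidate donor uniformly among the others and
#' copies the donor's current code with probability
#' `plogis(alpha_horizontal + beta_dist * z(dist) + beta_env * z(|dTH|))`,
#' with `z()` standardized over all candidate pairs of the world.
#'
#' @param tree `phylo` whose tip labels are the society ids.
#' @param societies Society tibble (`id`, `lat`, `lon`).
#' @param config A [world_config()] (supplies the trait parameters and seed).
#' @param th Named numeric vector of temperature-harshness scores per
#'   society id (used for the environmental bias).
#' @param n_traits Number of independent traits to simulate.
#' @return A tibble `society_id`, `trait_id`, `code`, `provenance`
#'   (`"vertical"` or `"horizontal"`).
#' @export
evolve_traits <- function(tree, societies, config, th, n_traits = 10) {
  validate_world_config(config)
  if (!setequal(tree$tip.label, societies$id)) {
    abort("tree tips must match society ids")
  }
  if (!all(societies$id %in% names(th))) {
    abort("th must be a named vector covering every society id")
  }
  n <- nrow(societies)
  dmat <- geodesic_matrix(societies)
  th_v <- th[societies$id]
  th_diff <- abs(outer(th_v, th_v, "-"))
  off <- upper.tri(dmat)
  z_d <- (dmat - mean(dmat[off])) / max(sd(dmat[off]), 1e-12)
  z_e <- (th_diff - mean(th_diff[off])) / max(sd(th_diff[off]), 1e-12)

  k <- config$n_trait_categories
  ord <- postorder_edges(tree)
  root <- ape::Ntip(tree) + 1L
  idx <- match(societies$id, tree$tip.label)

  with_stage_seed(stage_seed(config$seed, "traits"), {
    out <- vector("list", n_traits)
    for (t in seq_len(n_traits)) {
      node_code <- integer(max(tree$edge))
      node_code[root] <- sample.int(k, 1)
      for (e in ord) {                      # preorder: parent before child
        par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
        p_switch <- 1 - exp(-config$mu_vertical * tree$edge.length[e])
        node_code[child] <- if (runif(1) < p_switch) {
          resample_different(node_code[par], k)
        } else node_code[par]
      }
      code <- node_code[seq_len(ape::Ntip(tree))][idx]   # per society row
      prov <- rep("vertical", n)
      visit <- sample.int(n)
      for (i in visit) {
        donor <- if (n > 1) sample(setdiff(seq_len(n), i), 1) else i
        eta <- config$alpha_horizontal +
          config$beta_dist * z_d[i, donor] +
          config$beta_env * z_e[i, donor]
        if (is.finite(eta) && runif(1) < plogis(eta)) {
          code[i] <- code[donor]
          prov[i] <- "horizontal"
        }
      }
      out[[t]] <- tibble::tibble(
        society_id = societies$id,
        trait_id = sprintf("trait%02d", t),
        code = code, provenance = prov
      )
    }
    dplyr::bind_rows(out)
  })
}

resample_different <- function(code, k) {
  pool <- setdiff(seq_len(k), code)
  if (length(pool) == 1) pool else sample(pool, 1)
}

# edges ordered parent-before-child (preorder on the edge list)
postorder_edges <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  res <- integer(0)
  stack <- root
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  while (length(stack)) {
    node <- stack[[1]]; stack <- stack[-1]
    kid_edges <- children[[as.character(node)]]
    if (!is.null(kid_edges)) {
      res <- c(res, kid_edges)
      stack <- c(tree$edge[kid_edges, 2], stack)
    }
  }
  res
}

#' Simulate a complete synthetic world
#'
#' Runs every generator stage under substreams of the master seed and
#' returns the bundle downstream stages consume.
#'
#' @param config A [world_config()].
#' @param n_traits Number of traits for [evolve_traits()].
#' @param mask Optional land mask (logical matrix, `TRUE` = land); defaults
#'   to all-land.
#' @return A list of class `synthetic_world` with elements `config`,
#'   `climate`, `elevation`, `societies`, `tree`, `traits`, `env` (the
#'   [env_pca()] axes used for the trait bias), and `graph`.
#' @examples
#' \donttest{
#' w <- simulate_world(world_config(n_societies = 30, years = 10, seed = 5),
#'                     n_traits = 2)
#' names(w)
#' }
#' @export
simulate_world <- function(config, n_traits = 10, mask = NULL) {
  climate <- generate_climate(config)
  elevation <- generate_elevation(config)
  societies <- place_societies(config, mask)
  tree <- simulate_tree(config$n_societies,
                        seed = stage_seed(config$seed, "tree"))
  summ <- summarize_series(climate)
  env <- env_pca(summ)
  graph <- build_graph(climate$lat, climate$lon, mask = mask)
  th_grid <- axes_to_grid(env, "TH")
  soc_cells <- snap_to_cell(graph, societies$lat, societies$lon)
  th <- setNames(th_grid[cbind(graph$nodes$row[soc_cells],
                               graph$nodes$col[soc_cells])],
                 societies$id)
  traits <- evolve_traits(tree, societies, config, th, n_traits = n_traits)
  structure(
    list(config = config, climate = climate, elevation = elevation,
         societies = societies, tree = tree, traits = traits,
         env = env, graph = graph),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", x$config$grid_n_lat, "x", x$config$grid_n_lon,
      " grid, ", nrow(x$societies), " societies, ",
      dplyr::n_distinct(x$traits$trait_id), " traits\n", sep = "")
  invisible(x)
}

# n x n great-circle distance matrix (km) between society coordinates
geodesic_matrix <- function(societies) {
  m <- geosphere::distm(cbind(societies$lon, societies$lat),
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2, r = 6371008.8)
                        }) / 1000
  dimnames(m) <- list(societies$id, societies$id)
  m
}
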