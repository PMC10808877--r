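#' Configuration for a synthetic world
#'
#' Bundles every tunable of the synthetic-world generator: the grid geometry,
#' the monthly climate model, terrain roughness, society placement, the
#' trait-evolution parameters, and the master seed. The defaults describe a
#' mid-sized world (a 30 x 40 half-degree-style grid spanning 130 degrees of
#' latitude) with clearly latitudinally structured climate, which is the
#' regime the downstream analyses assume.
#'
#' Trait histories combine vertical inheritance along a Yule language tree
#' (per-branch switch probability `1 - exp(-mu_vertical * branch_length)`)
#' with a single horizontal copying pass in which society `i` copies a random
#' donor `j` with probability
#' `plogis(alpha_horizontal + beta_dist * z(distance_ij) + beta_env * z(|TH_i - TH_j|))`,
#' where `z()` standardizes over the realized candidate pairs so the slopes
#' are comparable across worlds.
#'
#' @param grid_n_lat,grid_n_lon Number of grid rows (latitude bands) and
#'   columns (longitude bands). At least 2 latitude bands are required.
#' @param lat_range,lon_range Length-2 numeric, extent in decimal degrees.
#' @param years Length of the monthly climate series in years (12 months per
#'   year are generated).
#' @param seasonality_amp Seasonal temperature amplitude (deg C) reached at the
#'   highest absolute latitude of the grid; amplitude grows linearly with
#'   `|lat|` and its phase flips across the equator.
#' @param noise_sd_temp,noise_sd_precip White-noise standard deviations for
#'   the monthly temperature (deg C) and precipitation (mm) fields.
#' @param precip_base Baseline monthly precipitation (mm) of the latitudinal
#'   wet-belt profile; must be non-negative.
#' @param elevation_scale Standard deviation (m) of the smooth elevation
#'   field; 0 gives a perfectly flat world.
#' @param n_societies Number of societies to place (one per sampled land
#'   cell, at the cell center).
#' @param n_trait_categories Number of discrete codes per trait (>= 3; the
#'   sharing analysis drops traits with <= 2 categories).
#' @param beta_env,beta_dist Log-odds slopes of the horizontal-copy
#'   probability on standardized temperature-harshness dissimilarity and
#'   standardized geodesic distance. Use `-Inf` to switch horizontal copying
#'   off entirely.
#' @param alpha_horizontal Baseline log-odds of a horizontal copy event
#'   (default `qlogis(0.25)`: a quarter of societies copy when both slopes
#'   are zero).
#' @param mu_vertical Trait switch rate per unit branch length in `[0, 1]`
#'   scale space: the switch probability on a branch of length `b` is
#'   `1 - exp(-mu_vertical * b)`.
#' @param seed Master seed; every stochastic stage derives its own substream
#'   from it so a world is fully reproducible.
#'
#' @return A list of class `world_config`.
#' @examples
#' cfg <- world_config(n_societies = 40, seed = 7)
#' cfg$grid_n_lat
#' @export
world_config <- function(grid_n_lat = 30, grid_n_lon = 40,
                         lat_range = c(-65, 65), lon_range = c(0, 60),
                         years = 30,
                         seasonality_amp = 10,
                         noise_sd_temp = 1,
                         noise_sd_precip = 20,
                         precip_base = 80,
                         elevation_scale = 1000,
                         n_societies = 150,
                         n_trait_categories = 5,
                         beta_env = 0, beta_dist = 0,
                         alpha_horizontal = qlogis(0.25),
                         mu_vertical = 0.05,
                         seed = 1L) {
  cfg <- list(
    grid_n_lat = as.integer(grid_n_lat), grid_n_lon = as.integer(grid_n_lon),
    lat_range = as.numeric(lat_range), lon_range = as.numeric(lon_range),
    years = as.integer(years),
    seasonality_amp = seasonality_amp,
    noise_sd_temp = noise_sd_temp, noise_sd_precip = noise_sd_precip,
    precip_base = precip_base, elevation_scale = elevation_scale,
    n_societies = as.integer(n_societies),
    n_trait_categories = as.integer(n_trait_categories),
    beta_env = beta_env, beta_dist = beta_dist,
    alpha_horizontal = alpha_horizontal,
    mu_vertical = mu_vertical,
    seed = as.integer(seed)
  )
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  stopifnot(
    cfg$grid_n_lat >= 2, cfg$grid_n_lon >= 1,
    cfg$grid_n_lat * cfg$grid_n_lon >= 2,
    length(cfg$lat_range) == 2, length(cfg$lon_range) == 2,
    diff(cfg$lat_range) > 0, diff(cfg$lon_range) > 0,
    cfg$years >= 1,
    cfg$noise_sd_temp >= 0, cfg$noise_sd_precip >= 0,
    cfg$precip_base >= 0, cfg$elevation_scale >= 0,
    cfg$n_societies >= 1, cfg$n_trait_categories >= 3,
    cfg$mu_vertical >= 0, cfg$mu_vertical <= 1
  )
  if (!is.finite(cfg$alpha_horizontal) && cfg$alpha_horizontal != -Inf) {
    abort("alpha_horizontal must be finite or -Inf")
  }
  for (b in c(cfg$beta_env, cfg$beta_dist)) {
    if (is.nan(b) || b == Inf) abort("beta parameters must be finite or -Inf")
  }
  if (cfg$lat_range[1] < -90 || cfg$lat_range[2] > 90) {
    abort("lat_range must lie within [-90, 90]")
  }
  invisible(cfg)
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config> ", x$grid_n_lat, "x", x$grid_n_lon, " grid, ",
      x$years, " years, ", x$n_societies, " societies, seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# deterministic per-stage substreams derived from the master seed
stage_seed <- function(seed, stage) {
  offs <- c(climate = 11L, elevation = 23L, societies = 37L,
            tree = 53L, traits = 71L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

# run expr under a temporary RNG state seeded with `seed`
with_stage_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
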