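#' Write / read a grid matrix as CSV with a JSON sidecar header
#'
#' Plain-text persistence for climate and elevation grids: the matrix goes
#' to `<path>.csv` (no row names) and the lat/lon axes to `<path>.json`.
#'
#' @param m Matrix with optional `lat`/`lon` attributes.
#' @param path Base path (without extension).
#' @param lat,lon Axis vectors (default from attributes).
#' @return `path`, invisibly.
#' @export
write_grid <- function(m, path, lat = attr(m, "lat"), lon = attr(m, "lon")) {
  utils::write.table(m, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n_lat = nrow(m), n_lon = ncol(m),
                            lat = lat, lon = lon),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == hdr$n_lat, ncol(m) == hdr$n_lon)
  attr(m, "lat") <- hdr$lat
  attr(m, "lon") <- hdr$lon
  m
}

#' Validate pipeline inputs
#'
#' Checks coordinate ranges, Newick-tip/society-id agreement, trait code
#' domains and the two-category rule, reporting every issue found.
#'
#' @param societies Society tibble.
#' @param trait_table Trait tibble.
#' @param tree Optional `phylo`.
#' @param config Optional `world_config` (to bound coordinates).
#' @return A tibble `severity` (`"error"`/`"warning"`), `message`;
#'   zero rows when everything checks out.
#' @export
validate_inputs <- function(societies, trait_table = NULL, tree = NULL,
                            config = NULL) {
  issues <- list()
  push <- function(sev, msg) {
    issues[[length(issues) + 1]] <<- tibble::tibble(severity = sev,
                                                    message = msg)
  }
  if (anyDuplicated(societies$id)) push("error", "duplicate society ids")
  bad_lat <- abs(societies$lat) > 90
  if (any(bad_lat)) {
    push("error", sprintf("latitude out of [-90,90] for: %s",
                          paste(societies$id[bad_lat], collapse = ", ")))
  }
  if (any(abs(societies$lon) > 180)) push("error", "longitude out of [-180,180]")
  if (!is.null(config)) {
    inside <- societies$lat >= config$lat_range[1] &
      societies$lat <= config$lat_range[2] &
      societies$lon >= config$lon_range[1] &
      societies$lon <= config$lon_range[2]
    if (!all(inside)) push("error", "societies outside the grid extent")
  }
  if (!is.null(tree)) {
    orphans <- setdiff(societies$id, tree$tip.label)
    if (length(orphans) > 0) {
      push("warning", sprintf("%d societies missing from the tree",
                              length(orphans)))
    }
  }
  if (!is.null(trait_table)) {
    unknown <- setdiff(unique(trait_table$society_id), societies$id)
    if (length(unknown) > 0) {
      push("error", sprintf("trait table references unknown societies: %s",
                            paste(head(unknown, 5), collapse = ", ")))
    }
    cats <- trait_table %>%
      dplyr::filter(!is.na(.data$code)) %>%
      dplyr::group_by(.data$trait_id) %>%
      dplyr::summarise(k = dplyr::n_distinct(.data$code), .groups = "drop")
    thin <- cats$trait_id[cats$k <= 2]
    if (length(thin) > 0) {
      push("warning", sprintf("traits with <= 2 categories (excluded): %s",
                              paste(thin, collapse = ", ")))
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(severity = character(0), message = character(0))
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Run the full synthetic-world pipeline
#'
#' Orchestrates simulate -> climate summaries/axes -> pairs -> barriers ->
#' sharing models -> origin comparison, writing every stage's tables under
#' `out_dir` together with a config echo and a manifest that records a
#' content hash per stage plus all exclusion counts. A stage whose hash
#' matches the manifest on disk and whose outputs exist is skipped, so
#' deleting one stage's outputs reruns only it and everything downstream.
#'
#' @param config A [world_config()] or a path to a YAML/JSON file of
#'   `world_config` fields.
#' @param out_dir Output directory (created if needed).
#' @param n_traits Traits to simulate.
#' @param k_neighbors Neighbours per society for the pair table.
#' @param n_origin_areas Circular origin areas planted on the synthetic
#'   map (societies within `origin_radius_km` of each area center).
#' @param origin_radius_km Area assignment radius.
#' @param mode Neighbourhood-transmission mode.
#' @param origin_k Neighbours per focal society in the corridor stage.
#' @param alpha Significance level.
#' @return Invisibly, a list with the stage objects (`world`, `pairs`,
#'   `barriers`, `sharing`, `origins`) and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir, n_traits = 10, k_neighbors = 20,
                         n_origin_areas = 4, origin_radius_km = 1500,
                         mode = "five_with_data", origin_k = 20,
                         alpha = 0.05) {
  if (is.character(config)) {
    fields <- if (grepl("[.]ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    config <- do.call(world_config, fields)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  } else list(stages = list())
  log <- list()
  run_cfg <- list(config = unclass(config), n_traits = n_traits,
                  k_neighbors = k_neighbors,
                  n_origin_areas = n_origin_areas,
                  origin_radius_km = origin_radius_km, mode = mode,
                  origin_k = origin_k, alpha = alpha)
  cfg_hash <- rlang::hash(run_cfg)

  fresh <- function(stage, files) {
    h <- manifest$stages[[stage]]
    !is.null(h) && identical(h, cfg_hash) &&
      all(file.exists(file.path(out_dir, files)))
  }
  mark <- function(stage) {
    manifest$stages[[stage]] <<- cfg_hash
  }

  jsonlite::write_json(run_cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  # -- simulate ---------------------------------------------------------
  world <- simulate_world(config, n_traits = n_traits)
  centers <- tibble::tibble(
    area = sprintf("area%02d", seq_len(n_origin_areas)),
    lat = quantile(world$societies$lat,
                   probs = seq(0.15, 0.85, length.out = n_origin_areas)),
    lon = quantile(world$societies$lon,
                   probs = seq(0.2, 0.8, length.out = n_origin_areas)))
  world$societies <- assign_origin_areas(world$societies, centers,
                                         radius_km = origin_radius_km)
  if (!fresh("simulate", c("societies.csv", "traits.csv", "tree.nwk"))) {
    write.csv(world$societies, file.path(out_dir, "societies.csv"),
              row.names = FALSE)
    write.csv(world$traits, file.path(out_dir, "traits.csv"),
              row.names = FALSE)
    ape::write.tree(world$tree, file.path(out_dir, "tree.nwk"))
    write_grid(world$elevation, file.path(out_dir, "elevation"))
    mark("simulate")
  }
  issues <- validate_inputs(world$societies, world$traits, world$tree, config)
  if (any(issues$severity == "error")) {
    abort(paste("input validation failed:",
                paste(issues$message[issues$severity == "error"],
                      collapse = "; ")))
  }
  log$validation_warnings <- sum(issues$severity == "warning")

  # -- climate ----------------------------------------------------------
  if (!fresh("climate", c("env_axes.csv", "env_loadings.csv"))) {
    write.csv(world$env$scores, file.path(out_dir, "env_axes.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(world$env$loadings),
              file.path(out_dir, "env_loadings.csv"))
    mark("climate")
  }

  # -- pairs + barriers -------------------------------------------------
  pairs <- nearest_pairs(world$societies, k = k_neighbors)
  barriers <- pair_barriers(pairs, world$societies, world$env,
                            world$elevation, world$graph)
  log$pairs_total <- nrow(pairs)
  log$pairs_disconnected <- sum(barriers$excluded)
  if (!fresh("barriers", "barriers.csv")) {
    write.csv(barriers, file.path(out_dir, "barriers.csv"),
              row.names = FALSE)
    mark("barriers")
  }

  # -- sharing models ---------------------------------------------------
  traits_rc <- recode_traits(world$traits)
  log$traits_dropped_two_category <- length(attr(traits_rc, "dropped_traits"))
  sharing <- fit_sharing(pairs, barriers, world$societies, traits_rc,
                         world$tree, mode = mode)
  log$models_excluded <- sum(!glance(sharing)$included)
  log$models_exclusion_reasons <- table(glance(sharing)$reason) |>
    as.list()
  if (!fresh("fit_sharing", c("sharing_results.csv", "sharing_models.csv"))) {
    write.csv(tidy(sharing), file.path(out_dir, "sharing_results.csv"),
              row.names = FALSE)
    write.csv(glance(sharing), file.path(out_dir, "sharing_models.csv"),
              row.names = FALSE)
    mark("fit_sharing")
  }

  # -- origin corridors -------------------------------------------------
  origins <- compare_origin_corridors(world$societies, barriers,
                                      range = "close", k = origin_k,
                                      alpha = alpha)
  if (!fresh("origins", "origin_group_stats.csv")) {
    gs <- purrr::imap(origins$fits, function(f, nm) {
      dplyr::mutate(f$group_stats, component = nm, .before = 1)
    }) |> dplyr::bind_rows()
    tk <- purrr::imap(origins$fits, function(f, nm) {
      dplyr::mutate(tidy(f), component = nm, .before = 1)
    }) |> dplyr::bind_rows()
    write.csv(gs, file.path(out_dir, "origin_group_stats.csv"),
              row.names = FALSE)
    write.csv(tk, file.path(out_dir, "origin_tukey.csv"), row.names = FALSE)
    write.csv(as.data.frame(origins$pca$loadings),
              file.path(out_dir, "origin_loadings.csv"))
    mark("origins")
  }

  manifest$config_hash <- cfg_hash
  manifest$log <- log
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(list(world = world, pairs = pairs, barriers = barriers,
                 sharing = sharing, origins = origins, manifest = manifest))
}
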