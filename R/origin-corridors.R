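#' Neighbour sets for a focal society
#'
#' The `k` geodesic-nearest other societies at distance at least `min_km`;
#' close range uses `min_km = 0`, long range the 2500 km threshold. Fewer
#' than `k` qualifying societies are returned with a warning.
#'
#' @param focal Focal society id.
#' @param societies Society tibble (`id`, `lat`, `lon`).
#' @param k Neighbour count.
#' @param min_km Minimum geodesic distance (km).
#' @return Character vector of neighbour ids, nearest first.
#' @export
neighbor_sets <- function(focal, societies, k = 100, min_km = 0) {
  i <- match(focal, societies$id)
  if (is.na(i)) abort(sprintf("unknown society '%s'", focal))
  d <- geodesic_km(societies$lat[i], societies$lon[i],
                   societies$lat, societies$lon)
  ok <- societies$id != focal & d >= min_km
  ord <- order(d[ok], societies$id[ok])
  nb <- societies$id[ok][ord]
  if (length(nb) < k) {
    warn(sprintf("only %d neighbours available for %s (k = %d)",
                 length(nb), focal, k))
  }
  head(nb, k)
}

#' Average barrier metrics over a focal society's neighbour set
#'
#' One row per focal society per range: the arithmetic mean of each of the
#' 9 barrier metrics + geodesic distance over the pairs linking the focal
#' society to its neighbour set, with the contributing-pair count.
#'
#' @param focal_ids Character vector of focal society ids.
#' @param societies Society tibble with an `origin_area` column.
#' @param barriers Pair-barrier table from [pair_barriers()] (keys sorted).
#' @param k,min_km Passed to [neighbor_sets()].
#' @param range_label Label stored in the `range` column.
#' @return A tibble, one row per focal society: `id`, `origin_area`,
#'   `range`, `n_pairs`, and the 9 metric means.
#' @export
average_barriers <- function(focal_ids, societies, barriers,
                             k = 100, min_km = 0, range_label = "close") {
  metrics <- c("th_dissim", "ai_dissim", "th_cost", "ai_cost",
               "th_len", "ai_len", "topo_cost", "topo_len", "geodesic_km")
  key <- paste(barriers$id_A, barriers$id_B)
  rows <- purrr::map(focal_ids, function(f) {
    nb <- suppressWarnings(neighbor_sets(f, societies, k = k, min_km = min_km))
    if (length(nb) == 0) return(NULL)
    idx <- match(paste(pmin(f, nb), pmax(f, nb)), key)
    idx <- idx[!is.na(idx)]
    sub <- barriers[idx, ]
    sub <- dplyr::filter(sub, !.data$excluded)
    if (nrow(sub) == 0) return(NULL)
    out <- tibble::tibble(id = f,
                          origin_area = societies$origin_area[
                            match(f, societies$id)],
                          range = range_label, n_pairs = nrow(sub))
    for (m in metrics) out[[m]] <- mean(sub[[m]])
    out
  })
  dplyr::bind_rows(rows)
}

#' Origin-area principal components of focal barrier profiles
#'
#' Varimax-rotated PCA of the focal-society barrier means: 3 components at
#' close range, 4 at long range, sign-anchored so high scores mean high
#' barriers, labelled by the dominant barrier family.
#'
#' @param focal_df An [average_barriers()] tibble.
#' @param range `"close"` (3 components) or `"long"` (4).
#' @return A `component_scores` object whose `scores` tibble carries the
#'   focal `id`, `origin_area`, and coordinates joined back on.
#' @export
origin_pca <- function(focal_df, range = c("close", "long")) {
  range <- match.arg(range)
  k <- if (range == "close") 3 else 4
  metrics <- c("th_dissim", "ai_dissim", "th_cost", "ai_cost",
               "th_len", "ai_len", "topo_cost", "topo_len", "geodesic_km")
  comps <- varimax_components(focal_df[, metrics], n_components = k,
                              min_rows = k + 2)
  comps$scores <- dplyr::bind_cols(
    focal_df[, intersect(c("id", "origin_area", "range"), names(focal_df))],
    comps$scores)
  comps$range <- range
  comps
}

#' Spatial weight matrix from symmetrized k-nearest neighbours
#'
#' Binary k-nearest-neighbour links, row-standardized, then symmetrized as
#' `(W + t(W)) / 2`.
#'
#' @param coords Data frame with `lat`, `lon`.
#' @param k Neighbours per point.
#' @return A dense symmetric weight matrix.
#' @export
knn_weights <- function(coords, k = 5) {
  n <- nrow(coords)
  dm <- geosphere::distm(cbind(coords$lon, coords$lat),
                         fun = function(p1, p2)
                           geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dm[i, -i])[seq_len(min(k, n - 1))]
    W[i, setdiff(seq_len(n), i)[nb]] <- 1
  }
  W <- W / pmax(rowSums(W), 1)
  (W + t(W)) / 2
}

#' Semi-parametric spatial eigenvector filtering
#'
#' Candidate spatial patterns are the eigenvectors of `M W M`, where `W` is
#' the symmetrized k-nearest-neighbour weight matrix and `M` the
#' residual-maker of the supplied design. Eigenvectors are added greedily:
#' at each step the candidate whose inclusion most shrinks `|Moran's I|` of
#' the residuals joins the design; selection stops when the residual
#' Moran's I permutation p-value exceeds `alpha` or no candidate improves.
#'
#' @param y Response vector.
#' @param X Design matrix (including intercept).
#' @param coords Data frame with `lat`, `lon`.
#' @param k Neighbours for the weight matrix.
#' @param alpha Stopping p-value.
#' @param n_perm Permutations for the Moran test.
#' @param max_vectors Safety cap on selected vectors.
#' @return A list: `vectors` (matrix, possibly 0 columns), `moran_initial`,
#'   `moran_final`, `p_final`, `n_selected`.
#' @export
spatial_filter_eigenvectors <- function(y, X, coords, k = 5, alpha = 0.1,
                                        n_perm = 199, max_vectors = 10) {
  n <- length(y)
  if (n < 10) {
    warn("fewer than 10 observations: spatial filtering skipped")
    return(list(vectors = matrix(numeric(0), n, 0),
                moran_initial = NA_real_, moran_final = NA_real_,
                p_final = NA_real_, n_selected = 0L))
  }
  W <- knn_weights(coords, k = k)
  M <- diag(n) - X %*% solve(crossprod(X), t(X))
  eg <- eigen(M %*% W %*% M, symmetric = TRUE)
  cand <- eg$vectors[, eg$values > 1e-9, drop = FALSE]

  moran_w <- function(z) {
    zz <- z - mean(z)
    ss <- sum(zz^2)
    if (ss == 0) return(NA_real_)
    n / sum(W) * as.numeric(t(zz) %*% W %*% zz) / ss
  }
  perm_p <- function(z) {
    obs <- moran_w(z)
    perm <- vapply(seq_len(n_perm), function(s) moran_w(sample(z)),
                   numeric(1))
    (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  }
  resid_of <- function(Xc) {
    y - Xc %*% solve(crossprod(Xc), crossprod(Xc, y))
  }
  Xc <- X
  sel <- integer(0)
  r <- as.numeric(resid_of(Xc))
  I0 <- moran_w(r)
  repeat {
    p <- perm_p(r)
    if (is.na(p) || p > alpha || length(sel) >= max_vectors ||
        length(sel) >= ncol(cand)) break
    pool <- setdiff(seq_len(ncol(cand)), sel)
    scores <- vapply(pool, function(j) {
      abs(moran_w(as.numeric(resid_of(cbind(Xc, cand[, j])))))
    }, numeric(1))
    best <- pool[which.min(scores)]
    if (min(scores) >= abs(moran_w(r))) break   # no candidate improves
    sel <- c(sel, best)
    Xc <- cbind(Xc, cand[, best])
    r <- as.numeric(resid_of(Xc))
  }
  list(vectors = cand[, sel, drop = FALSE],
       moran_initial = I0, moran_final = moran_w(r),
       p_final = perm_p(r), n_selected = length(sel))
}

#' Variance-weighted comparison of origin areas with Tukey contrasts
#'
#' Two-stage fit of a PC score against the origin-area factor: OLS first,
#' then weights `1 / var_hat(area residuals)` and a weighted refit.
#' Optionally, spatial eigenvectors selected by
#' [spatial_filter_eigenvectors()] against the area design enter the
#' weighted model as covariates. All-pairs Tukey honest significant
#' differences use the weighted fit's adjusted means and covariance with
#' the studentized-range distribution on the weighted residual df.
#' Areas with fewer than 2 rows are dropped (their variance is
#' inestimable).
#'
#' @param data Tibble with the response, an area column, and `lat`/`lon`
#'   (required when `spatial_filter = TRUE`).
#' @param response Name of the PC score column.
#' @param area Name of the area factor column.
#' @param spatial_filter Apply eigenvector filtering.
#' @param alpha Significance level for flagging Tukey pairs.
#' @param ... Passed to [spatial_filter_eigenvectors()].
#' @return An object of class `corridor_fit`: list with `group_stats`
#'   (area, n, mean, sd, fitted_mean), `tukey` (area_i, area_j, diff, se,
#'   q, p, significant), `fit` (the weighted `lm`), `filter` (spatial
#'   filtering summary), `response`, `alpha`.
#' @export
fit_weighted_lm <- function(data, response, area = "origin_area",
                            spatial_filter = TRUE, alpha = 0.05, ...) {
  df <- dplyr::filter(data, !is.na(.data[[area]]), !is.na(.data[[response]]))
  counts <- table(df[[area]])
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    inform(sprintf("fit_weighted_lm: areas dropped (<2 societies): %s",
                   paste(small, collapse = ", ")))
    df <- dplyr::filter(df, !(.data[[area]] %in% small))
  }
  df[[area]] <- droplevels(factor(df[[area]]))
  areas <- levels(df[[area]])
  if (length(areas) < 2) abort("at least two areas are required")
  y <- df[[response]]
  X <- stats::model.matrix(~ df[[area]])
  colnames(X) <- c("(Intercept)", paste0("area_", areas[-1]))

  ols <- lm(y ~ 0 + X)
  v_by_area <- tapply(residuals(ols), df[[area]], function(r) {
    max(var(r), 1e-10)
  })
  w <- 1 / v_by_area[as.character(df[[area]])]

  filt <- NULL; E <- NULL
  if (spatial_filter) {
    filt <- spatial_filter_eigenvectors(y, X, df[, c("lat", "lon")], ...)
    if (filt$n_selected > 0) E <- filt$vectors
  }
  Xf <- if (is.null(E)) X else cbind(X, ev = E)
  wfit <- lm(y ~ 0 + Xf, weights = as.numeric(w))

  b <- coef(wfit); V <- vcov(wfit)
  # adjusted area means from the weighted fit
  Ca <- matrix(0, length(areas), length(b))
  colnames(Ca) <- names(b)
  Ca[, 1] <- 1
  for (j in seq_along(areas[-1])) Ca[j + 1, j + 1] <- 1
  mu <- as.numeric(Ca %*% b)
  Vmu <- Ca %*% V %*% t(Ca)
  dfres <- wfit$df.residual

  pr <- t(utils::combn(seq_along(areas), 2))
  diffs <- mu[pr[, 1]] - mu[pr[, 2]]
  se <- sqrt(Vmu[cbind(pr[, 1], pr[, 1])] + Vmu[cbind(pr[, 2], pr[, 2])] -
               2 * Vmu[cbind(pr[, 1], pr[, 2])])
  q <- sqrt(2) * abs(diffs) / se
  pvals <- ptukey(q, nmeans = length(areas), df = dfres, lower.tail = FALSE)
  tukey <- tibble::tibble(
    area_i = areas[pr[, 1]], area_j = areas[pr[, 2]],
    diff = diffs, se = se, q = q, p = pvals,
    significant = pvals < alpha)

  gs <- df %>%
    dplyr::group_by(area = .data[[area]]) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[response]]),
                     sd = sd(.data[[response]]), .groups = "drop") %>%
    dplyr::mutate(fitted_mean = mu[match(.data$area, areas)])

  structure(list(group_stats = gs, tukey = tukey, fit = wfit,
                 filter = filt, response = response, alpha = alpha),
            class = "corridor_fit")
}

#' @export
print.corridor_fit <- function(x, ...) {
  cat("<corridor_fit> ", x$response, ": ", nrow(x$group_stats), " areas, ",
      sum(x$tukey$significant), "/", nrow(x$tukey),
      " Tukey pairs significant at alpha=", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Full origin-corridor comparison for one range
#'
#' Chains [average_barriers()], [origin_pca()] and one [fit_weighted_lm()]
#' per component.
#'
#' @param societies Society tibble with `origin_area` labels.
#' @param barriers Pair-barrier table covering the focal pairs.
#' @param range `"close"` or `"long"`.
#' @param k Neighbours per focal society.
#' @param min_km Long-range distance floor (used when `range = "long"`).
#' @param spatial_filter,alpha Passed to [fit_weighted_lm()].
#' @return A list of class `corridor_comparison`: `focal` (the averaged
#'   metrics), `pca` (`component_scores`), `fits` (named list of
#'   `corridor_fit` per component).
#' @export
compare_origin_corridors <- function(societies, barriers,
                                     range = c("close", "long"),
                                     k = 100, min_km = 2500,
                                     spatial_filter = TRUE, alpha = 0.05) {
  range <- match.arg(range)
  focal_ids <- societies$id[!is.na(societies$origin_area)]
  if (length(focal_ids) < 5) abort("too few focal societies with areas")
  focal <- average_barriers(focal_ids, societies, barriers, k = k,
                            min_km = if (range == "long") min_km else 0,
                            range_label = range)
  pca <- origin_pca(focal, range = range)
  sc <- pca$scores %>%
    dplyr::left_join(societies[, c("id", "lat", "lon")], by = "id")
  fits <- purrr::map(
    setNames(colnames(pca$loadings), unname(pca$labels)),
    function(cc) {
      fit_weighted_lm(sc, response = cc, spatial_filter = spatial_filter,
                      alpha = alpha)
    })
  structure(list(focal = focal, pca = pca, fits = fits, range = range),
            class = "corridor_comparison")
}

#' @export
print.corridor_comparison <- function(x, ...) {
  cat("<corridor_comparison> range=", x$range, ", ",
      nrow(x$focal), " focal societies, components: ",
      paste(names(x$fits), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Re-run the corridor comparison under reconstructed climates
#'
#' For each timepoint's climate stack, re-derives the environmental axes
#' and the TH/AI-based barrier columns, while reusing the topographic and
#' geodesic values from the baseline barrier table (they do not depend on
#' climate), then repeats the comparison.
#'
#' @param climates Named list of `climate_stack`s (e.g. `present`,
#'   `12kya`, ...).
#' @param base_barriers Baseline [pair_barriers()] table supplying the
#'   reused `topo_cost`, `topo_len`, `geodesic_km` columns.
#' @param pairs,societies,elev_grid,graph As elsewhere.
#' @param range,k,min_km,spatial_filter,alpha Passed through.
#' @return Named list of `corridor_comparison`, keyed by timepoint.
#' @export
paleo_rerun <- function(climates, base_barriers, pairs, societies,
                        elev_grid, graph, range = "close", k = 100,
                        min_km = 2500, spatial_filter = TRUE, alpha = 0.05) {
  purrr::imap(climates, function(cl, label) {
    env <- env_pca(summarize_series(cl))
    bar <- pair_barriers(pairs, societies, env, elev_grid, graph)
    reuse <- c("topo_cost", "topo_len", "geodesic_km")
    idx <- match(paste(bar$id_A, bar$id_B),
                 paste(base_barriers$id_A, base_barriers$id_B))
    for (cc in reuse) bar[[cc]] <- base_barriers[[cc]][idx]
    compare_origin_corridors(societies, bar, range = range, k = k,
                             min_km = min_km,
                             spatial_filter = spatial_filter, alpha = alpha)
  })
}
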