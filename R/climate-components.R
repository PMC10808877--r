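#' Colwell's predictability of a periodic series
#'
#' Splits the predictability of a monthly series into constancy (the series
#' tends to sit in the same state year-round) and contingency (the state is
#' predictable from the month). The series is discretized into `n_states`
#' equal-width bins between its minimum and maximum (optionally after a
#' `log1p` transform, the convention used here for precipitation), a
#' 12 x `n_states` month-by-state frequency table is formed, and the
#' Shannon-entropy decomposition gives
#' `C = 1 - H(state)/log(s)`,
#' `M = (H(month) + H(state) - H(month, state))/log(s)`, and
#' `P = C + M = 1 - (H(month, state) - H(month))/log(s)`.
#'
#' A constant series (all observations in one state) has zero conditional
#' entropy and returns `P = 1`, `C = 1`, `M = 0` by convention.
#'
#' @param series Numeric vector of monthly values; length must be a multiple
#'   of 12. If `discretize = FALSE` the values are taken to already be
#'   integer states in `1:n_states`.
#' @param n_states Number of discrete states (>= 2).
#' @param transform `"none"` or `"log1p"` (applied before binning).
#' @param discretize Set to `FALSE` when `series` is already discrete.
#' @return A tibble with one row: `P`, `C`, `M`, all in `[0, 1]` with
#'   `P = C + M`.
#' @examples
#' colwell_P(rep(sin(2 * pi * (0:11) / 12), 20))  # strict seasonality: P = 1
#' @export
colwell_P <- function(series, n_states = 11, transform = c("none", "log1p"),
                      discretize = TRUE) {
  transform <- match.arg(transform)
  if (length(series) %% 12 != 0) {
    abort("series length must be a multiple of 12")
  }
  if (n_states < 2) abort("n_states must be >= 2")
  if (any(!is.finite(series))) abort("series contains non-finite values")
  if (transform == "log1p") series <- log1p(series)

  if (discretize) {
    rng <- range(series)
    if (diff(rng) == 0) {
      return(tibble::tibble(P = 1, C = 1, M = 0))
    }
    state <- pmin(n_states,
                  1L + floor((series - rng[1]) / diff(rng) * n_states))
  } else {
    state <- as.integer(series)
    if (any(state < 1 | state > n_states)) {
      abort("discrete states must lie in 1:n_states")
    }
  }
  month <- rep_len(1:12, length(series))
  N <- table(factor(month, levels = 1:12),
             factor(state, levels = seq_len(n_states)))
  Z <- sum(N)
  Hx <- shannon(rowSums(N) / Z)          # uncertainty over months
  Hy <- shannon(colSums(N) / Z)          # uncertainty over states
  Hxy <- shannon(as.vector(N) / Z)
  logs <- log(n_states)
  C <- 1 - Hy / logs
  M <- (Hx + Hy - Hxy) / logs
  P <- 1 - (Hxy - Hx) / logs
  tibble::tibble(P = P, C = C, M = M)
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Summarize per-cell climate series
#'
#' Computes the six inputs of the environmental PCA for every land cell:
#' mean, variability and Colwell predictability of temperature and of
#' precipitation. Variability is the standard deviation of monthly values
#' for temperature and the coefficient of variation for precipitation;
#' predictability uses [colwell_P()] with `n_states` equal-width bins
#' (precipitation on the `log1p` scale). Cells containing any non-finite
#' month are excluded with a message.
#'
#' @param climate A `climate_stack` from [generate_climate()] (or any list
#'   with `temp`/`precip` arrays and `lat`/`lon` vectors).
#' @param n_states Bin count for [colwell_P()].
#' @return A tibble with one row per retained cell: `cell`, `row`, `col`,
#'   `lat`, `lon`, `temp_mean`, `temp_var`, `temp_pred`, `precip_mean`,
#'   `precip_var`, `precip_pred`.
#' @export
summarize_series <- function(climate, n_states = 11) {
  dims <- dim(climate$temp)
  if (dims[3] < 120) abort("at least 10 years of monthly data are required")
  nr <- dims[1]; nc <- dims[2]
  cells <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  res <- purrr::pmap(cells, function(row, col) {
    ts_t <- climate$temp[row, col, ]
    ts_p <- climate$precip[row, col, ]
    if (any(!is.finite(ts_t)) || any(!is.finite(ts_p))) return(NULL)
    cw_t <- colwell_P(ts_t, n_states = n_states)
    cw_p <- colwell_P(ts_p, n_states = n_states, transform = "log1p")
    pm <- mean(ts_p)
    tibble::tibble(
      row = row, col = col,
      lat = climate$lat[row], lon = climate$lon[col],
      temp_mean = mean(ts_t), temp_var = sd(ts_t), temp_pred = cw_t$P,
      precip_mean = pm,
      precip_var = if (pm > 0) sd(ts_p) / pm else 0,
      precip_pred = cw_p$P
    )
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0) {
    inform(sprintf("summarize_series: %d cells with non-finite months excluded",
                   dropped))
  }
  out <- dplyr::bind_rows(res)
  dplyr::mutate(out, cell = dplyr::row_number(), .before = 1)
}

#' Environmental axes: temperature harshness and aridity index
#'
#' Principal component analysis on the correlation matrix of the six climate
#' summaries over land cells. The first two components are returned as the
#' temperature-harshness (TH) and aridity-index (AI) axes, with signs
#' anchored deterministically so that harsh (cold, variable, unpredictable
#' temperature) and arid (dry, variable, unpredictable precipitation)
#' conditions score high: a component is flipped when the `temp_mean`
#' (PC1) or `precip_mean` (PC2) loading is positive. Constant columns are
#' dropped with a warning (they cannot be standardized).
#'
#' @param summary A [summarize_series()] tibble.
#' @return An object of class `env_axes`: list with `scores` (tibble `cell`,
#'   `row`, `col`, `lat`, `lon`, `TH`, `AI`), `loadings` (variables x 2),
#'   `var_explained` (length-2 fractions), and `sdev`.
#' @export
env_pca <- function(summary) {
  vars <- c("temp_mean", "temp_var", "temp_pred",
            "precip_mean", "precip_var", "precip_pred")
  vars <- intersect(vars, names(summary))
  X <- as.matrix(summary[, vars])
  if (nrow(X) < 6) abort("at least 6 cells are required for the PCA")
  keep <- apply(X, 2, function(v) sd(v) > 0)
  if (!all(keep)) {
    warn(paste("constant columns dropped:",
               paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 2) abort("fewer than 2 non-constant columns; PCA impossible")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  load <- pc$rotation[, 1:2, drop = FALSE]
  scores <- pc$x[, 1:2, drop = FALSE]

  anchor <- c(PC1 = "temp_mean", PC2 = "precip_mean")
  for (j in 1:2) {
    av <- anchor[[j]]
    ref <- if (av %in% rownames(load)) load[av, j] else load[1, j]
    if (ref > 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(load) <- colnames(scores) <- c("TH", "AI")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = dplyr::bind_cols(
        summary[, c("cell", "row", "col", "lat", "lon")],
        tibble::as_tibble(scores)),
      loadings = load,
      var_explained = ve[1:2],
      sdev = pc$sdev[1:2]
    ),
    class = "env_axes")
}

#' @export
print.env_axes <- function(x, ...) {
  cat("<env_axes> ", nrow(x$scores), " cells; var explained TH=",
      round(x$var_explained[1], 3), ", AI=", round(x$var_explained[2], 3),
      "\n", sep = "")
  invisible(x)
}

#' Spread an environmental axis back onto the grid
#'
#' @param env An `env_axes` object.
#' @param axis `"TH"` or `"AI"`.
#' @return A matrix indexed by grid row/col (NA where the axis has no cell).
#' @export
axes_to_grid <- function(env, axis = c("TH", "AI")) {
  axis <- match.arg(axis)
  s <- env$scores
  m <- matrix(NA_real_, max(s$row), max(s$col))
  m[cbind(s$row, s$col)] <- s[[axis]]
  m
}
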