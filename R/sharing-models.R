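#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing column `j`
#' on the remaining columns (with intercept). A perfectly collinear column
#' reports `Inf`.
#'
#' @param X Numeric matrix or data frame of predictors (n > p).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) abort("vif requires n > p")
  if (any(!is.finite(X))) abort("vif requires finite columns")
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- suppressWarnings(
      summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |>
    setNames(colnames(X))
}

#' Reduce raw barrier predictors to varimax-rotated components
#'
#' Standardizes the columns, runs a correlation-matrix PCA, retains
#' `n_components`, applies a varimax rotation (tolerance 1e-6, no Kaiser
#' normalization, so the result is deterministic) and returns unit-variance
#' rotated scores. Each component is sign-anchored so its largest-|loading|
#' raw variable loads positively (high score = high barrier), and labelled
#' by the barrier family its dominant loadings belong to.
#'
#' @param X Data frame/matrix of raw predictors (rows = pairs or focal
#'   societies).
#' @param n_components Number of rotated components to keep.
#' @param min_rows Minimum complete rows; fewer is an error (the per-trait
#'   pipeline uses this to skip under-sampled traits).
#' @return An object of class `component_scores`: list with `scores`
#'   (tibble, one column per component), `loadings` (raw vars x
#'   components), `labels`, and `var_explained` of the retained subspace.
#' @export
varimax_components <- function(X, n_components = 5, min_rows = 50) {
  X <- as.matrix(X)
  if (nrow(X) < min_rows) {
    abort(sprintf("only %d complete rows (< %d)", nrow(X), min_rows))
  }
  if (n_components > ncol(X)) abort("n_components exceeds column count")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  k <- n_components
  L <- pc$rotation[, 1:k, drop = FALSE] %*% diag(pc$sdev[1:k], k, k)
  vr <- stats::varimax(L, normalize = FALSE, eps = 1e-6)
  Lr <- L %*% vr$rotmat
  # unit-variance standardized scores, rotated with the same orthogonal map
  S <- pc$x[, 1:k, drop = FALSE] %*% diag(1 / pc$sdev[1:k], k, k) %*% vr$rotmat
  for (j in seq_len(k)) {
    if (Lr[which.max(abs(Lr[, j])), j] < 0) {
      Lr[, j] <- -Lr[, j]; S[, j] <- -S[, j]
    }
  }
  labels <- component_labels(Lr)
  colnames(Lr) <- colnames(S) <- names(labels)
  structure(
    list(scores = tibble::as_tibble(S), loadings = Lr, labels = labels,
         var_explained = sum(pc$sdev[1:k]^2) / sum(pc$sdev^2)),
    class = "component_scores")
}

# map components to barrier families by their dominant |loading|
component_labels <- function(L) {
  fam <- c(th_dissim = "tempTurnover", th_cost = "tempTurnover",
           ai_dissim = "ariTurnover", ai_cost = "ariTurnover",
           th_len = "travelCost", ai_len = "travelCost",
           topo_cost = "travelCost", topo_len = "travelCost",
           geodesic_km = "travelCost",
           relatedness = "ancestry", neighbor_trans = "neighborTrans")
  raw <- rownames(L) %||% paste0("x", seq_len(nrow(L)))
  lab <- vapply(seq_len(ncol(L)), function(j) {
    top <- raw[which.max(abs(L[, j]))]
    if (top %in% names(fam)) fam[[top]] else top
  }, character(1))
  # disambiguate duplicates deterministically
  make.unique(lab, sep = "_") |> setNames(paste0("RC", seq_along(lab)))
}

#' @export
print.component_scores <- function(x, ...) {
  cat("<component_scores> ", ncol(x$scores), " components over ",
      nrow(x$scores), " rows; subspace variance ",
      round(x$var_explained, 3), "\n", sep = "")
  invisible(x)
}

#' Bernoulli mixed model of cultural sharing with society random intercepts
#'
#' Fits `logit P(share = 1) = b0 + X b + u[id_A] + u[id_B]` where `u` is a
#' single society-level random intercept with one shared variance: a
#' society contributes the same intercept whether it appears on the A or B
#' side of a pair. The multimembership structure is built through lme4's
#' modular interface (the random-effect design matrix is the sum of the two
#' id indicator matrices) and estimated by the Laplace approximation; Wald
#' tests are reported for the fixed effects.
#'
#' @param data Tibble with the response, predictors and both id columns.
#' @param response Name of the binary response column.
#' @param predictors Character vector of predictor column names.
#' @param id_cols Length-2 character vector naming the two society id
#'   columns.
#' @return An object of class `sharing_fit` with elements `coefficients`
#'   (tibble `term`, `estimate`, `std_error`, `statistic`, `p_value`),
#'   `sigma2` (random-intercept variance), `auc`, `n`, `share_fraction`,
#'   `converged`, and the underlying `merMod` as `fit`.
#' @export
fit_mixed_logit <- function(data, response = "share",
                            predictors = NULL,
                            id_cols = c("id_A", "id_B")) {
  y <- data[[response]]
  if (!all(y %in% c(0, 1))) abort("response must be binary 0/1")
  if (is.null(predictors)) {
    predictors <- setdiff(names(data), c(response, id_cols))
  }
  socs <- sort(unique(c(as.character(data[[id_cols[1]]]),
                        as.character(data[[id_cols[2]]]))))
  if (length(y) < length(socs)) {
    abort("fewer pairs than societies: the random-intercept design is degenerate")
  }
  df <- data.frame(..y = y, data[, predictors, drop = FALSE],
                   check.names = FALSE)
  # placeholder grouping factor covering every society level exactly once
  # at minimum (lme4 drops unused levels); its Zt is replaced below
  df$..g <- factor(rep_len(socs, length(y)), levels = socs)
  fml <- as.formula(paste("..y ~",
                          paste(sprintf("`%s`", predictors), collapse = " + "),
                          "+ (1 | ..g)"))
  fA <- factor(as.character(data[[id_cols[1]]]), levels = socs)
  fB <- factor(as.character(data[[id_cols[2]]]), levels = socs)

  fit <- NULL; converged <- FALSE
  msgs <- character(0)
  withCallingHandlers({
    gf <- lme4::glFormula(fml, data = df, family = stats::binomial())
    Zt <- Matrix::fac2sparse(fA, drop.unused.levels = FALSE) +
      Matrix::fac2sparse(fB, drop.unused.levels = FALSE)
    gf$reTrms$Zt <- Zt
    gf$reTrms$Ztlist[[1]] <- Zt
    devfun <- do.call(lme4::mkGlmerDevfun, gf)
    # the deviance closure resolves lme4 internals by scope; rebase its
    # environment onto the lme4 namespace so the modular fit works from
    # package code
    e_old <- environment(devfun)
    e_new <- new.env(parent = asNamespace("lme4"))
    for (nm in ls(e_old, all.names = TRUE)) assign(nm, get(nm, e_old), e_new)
    environment(devfun) <- e_new
    opt0 <- lme4::optimizeGlmer(devfun)
    devfun2 <- lme4::updateGlmerDevfun(devfun, gf$reTrms)
    opt <- lme4::optimizeGlmer(devfun2, stage = 2)
    fit <- lme4::mkMerMod(environment(devfun2), opt, gf$reTrms, fr = gf$fr)
    converged <- isTRUE(opt$conv == 0)
  }, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  if (any(grepl("failed to converge|convergence", msgs, ignore.case = TRUE))) {
    converged <- FALSE
  }
  ct <- summary(fit)$coefficients
  prob <- fitted(fit)
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(ct),
        estimate = unname(ct[, "Estimate"]),
        std_error = unname(ct[, "Std. Error"]),
        statistic = unname(ct[, "z value"]),
        p_value = unname(ct[, "Pr(>|z|)"])),
      sigma2 = as.numeric(lme4::VarCorr(fit)[["..g"]]),
      auc = auc_rank(y, prob),
      n = length(y),
      share_fraction = mean(y),
      converged = converged,
      messages = msgs,
      fit = fit),
    class = "sharing_fit")
}

#' @export
print.sharing_fit <- function(x, ...) {
  cat("<sharing_fit> n=", x$n, ", AUC=", round(x$auc, 3),
      ", sigma2=", signif(x$sigma2, 3),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Model inclusion filters
#'
#' Applies the three exclusion rules for per-trait models: share fraction
#' above 90% or below 10% (imbalance), fewer than 50 datapoints, or
#' non-convergence.
#'
#' @param share_fraction,n,converged Scalars describing a fitted model
#'   (a `sharing_fit` can be passed as the first argument instead).
#' @return A list `include` (logical) and `reason` (`NA` or one of
#'   `"imbalanced"`, `"too_few"`, `"not_converged"`).
#' @export
model_filters <- function(share_fraction, n = NULL, converged = NULL) {
  if (inherits(share_fraction, "sharing_fit")) {
    f <- share_fraction
    share_fraction <- f$share_fraction; n <- f$n; converged <- f$converged
  }
  reason <- NA_character_
  if (n < 50) reason <- "too_few"
  else if (share_fraction > 0.9 || share_fraction < 0.1) reason <- "imbalanced"
  else if (!isTRUE(converged)) reason <- "not_converged"
  list(include = is.na(reason), reason = reason)
}

#' Benjamini-Yekutieli false-discovery-rate adjustment
#'
#' Step-up adjustment with the harmonic correction factor `sum(1/i)`,
#' valid under arbitrary dependence; wraps `stats::p.adjust(method = "BY")`.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (never smaller than the input).
#' @export
adjust_fdr <- function(p) p.adjust(p, method = "BY")

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties contributing 1/2.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores (e.g. fitted probabilities).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Moran's I given directed index pairs (i, j) of the weight graph
morans_i_pairs <- function(x, i, j) {
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) return(NA_real_)
  length(x) / length(i) * sum(z[i] * z[j]) / ss
}

#' Moran's I spatial autocorrelogram with permutation tests
#'
#' Distance-binned Moran's I of model residuals using binary within-bin
#' weights; coordinates are typically pair midpoints. Bins are equal-count
#' up to the 90th percentile of inter-point distances. The permutation p
#' per bin is one-sided (observed or larger under label shuffles). Bins
#' with degenerate variance or no linked points return `NA` and a flag.
#'
#' @param residuals Numeric vector.
#' @param coords Matrix/data frame with columns `lat`, `lon` (same rows).
#' @param n_bins Number of equal-count distance bins.
#' @param n_perm Number of permutations.
#' @return An object of class `correlogram`: tibble `bin`, `center_km`,
#'   `lower_km`, `upper_km`, `n_links`, `I`, `p_perm`, `degenerate`.
#' @export
morans_correlogram <- function(residuals, coords, n_bins = 10, n_perm = 199) {
  n <- length(residuals)
  stopifnot(nrow(coords) == n)
  dm <- geosphere::distm(cbind(coords$lon, coords$lat),
                         fun = function(p1, p2)
                           geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  d <- dm[ut]
  dmax <- quantile(d, 0.9)
  keep <- d <= dmax & d > 0
  ut <- ut[keep, , drop = FALSE]; d <- d[keep]
  edges <- quantile(d, probs = seq(0, 1, length.out = n_bins + 1))
  edges[1] <- 0
  binid <- cut(d, breaks = unique(edges), include.lowest = TRUE,
               labels = FALSE)
  rows <- purrr::map(seq_len(max(binid, na.rm = TRUE)), function(b) {
    sel <- which(binid == b)
    i <- c(ut[sel, 1], ut[sel, 2]); j <- c(ut[sel, 2], ut[sel, 1])
    I_obs <- if (length(sel) == 0) NA_real_ else
      morans_i_pairs(residuals, i, j)
    degenerate <- length(sel) == 0 || is.na(I_obs)
    p_perm <- NA_real_
    if (!degenerate) {
      perm <- vapply(seq_len(n_perm), function(s) {
        morans_i_pairs(sample(residuals), i, j)
      }, numeric(1))
      p_perm <- (1 + sum(perm >= I_obs)) / (n_perm + 1)
    }
    tibble::tibble(bin = b, center_km = mean(range(d[sel])),
                   lower_km = min(d[sel]), upper_km = max(d[sel]),
                   n_links = length(sel), I = I_obs, p_perm = p_perm,
                   degenerate = degenerate)
  })
  structure(dplyr::bind_rows(rows), class = c("correlogram", "tbl_df",
                                              "tbl", "data.frame"))
}

#' Per-trait sharing pipeline and multi-trait driver
#'
#' For each trait: assembles the 11-predictor pair table, records the raw
#' VIFs, reduces to 5 varimax components, fits the mixed logit, applies
#' the inclusion filters and records the AUC. Raw p-values are then
#' BY-adjusted within each component family across all included traits.
#'
#' @param pairs,barriers,societies,trait_table,tree As produced upstream.
#' @param traits Character vector of trait ids (default: all in
#'   `trait_table`).
#' @param mode Neighbourhood-transmission mode.
#' @param n_components Rotated components to retain.
#' @return An object of class `sharing_results`: list with `results` (long
#'   tibble: trait, component, label, estimate, std_error, p_value,
#'   p_adjusted), `models` (per-trait tibble: trait, n, share_fraction,
#'   auc, converged, included, reason, max_vif), and `fits` (named list of
#'   `sharing_fit`s plus their component loadings).
#' @export
fit_sharing <- function(pairs, barriers, societies, trait_table, tree,
                        traits = NULL, mode = c("five_with_data", "ten_any"),
                        n_components = 5) {
  mode <- match.arg(mode)
  if (is.null(traits)) traits <- sort(unique(trait_table$trait_id))
  preds <- c("th_dissim", "ai_dissim", "th_cost", "th_len", "ai_cost",
             "ai_len", "topo_cost", "topo_len", "geodesic_km",
             "relatedness", "neighbor_trans")
  fits <- list(); model_rows <- list(); coef_rows <- list()
  for (tr in traits) {
    df <- assemble_pair_covariates(pairs, barriers, societies, trait_table,
                                   tree, tr, mode = mode)
    if (nrow(df) < 50) {
      model_rows[[tr]] <- tibble::tibble(
        trait = tr, n = nrow(df), share_fraction = NA_real_,
        auc = NA_real_, converged = NA, included = FALSE,
        reason = "too_few", max_vif = NA_real_)
      next
    }
    vifs <- vif(df[, preds])
    comps <- varimax_components(df[, preds], n_components = n_components)
    fit_df <- dplyr::bind_cols(df[, c("id_A", "id_B", "share")],
                               comps$scores)
    fit <- fit_mixed_logit(fit_df, response = "share",
                           predictors = colnames(comps$scores))
    flt <- model_filters(fit)
    fits[[tr]] <- list(fit = fit, components = comps, vif = vifs)
    model_rows[[tr]] <- tibble::tibble(
      trait = tr, n = fit$n, share_fraction = fit$share_fraction,
      auc = fit$auc, converged = fit$converged,
      included = flt$include, reason = flt$reason,
      max_vif = max(vifs))
    if (flt$include) {
      cf <- dplyr::filter(fit$coefficients, .data$term != "(Intercept)")
      coef_rows[[tr]] <- dplyr::mutate(
        cf, trait = tr,
        label = unname(comps$labels[.data$term]), .before = 1)
    }
  }
  results <- dplyr::bind_rows(coef_rows)
  if (nrow(results) > 0) {
    results <- results %>%
      dplyr::group_by(.data$label) %>%
      dplyr::mutate(p_adjusted = adjust_fdr(.data$p_value)) %>%
      dplyr::ungroup()
  }
  structure(list(results = results,
                 models = dplyr::bind_rows(model_rows),
                 fits = fits, mode = mode),
            class = "sharing_results")
}

#' @export
print.sharing_results <- function(x, ...) {
  cat("<sharing_results> ", nrow(x$models), " traits, ",
      sum(x$models$included), " included (mode ", x$mode, ")\n", sep = "")
  invisible(x)
}
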