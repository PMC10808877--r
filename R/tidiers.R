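#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a sharing_fit
#'
#' One row per fixed-effect term with estimate, standard error, Wald z and
#' p-value.
#'
#' @param x A `sharing_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy sharing_fit
tidy.sharing_fit <- function(x, ...) x$coefficients

#' One-row model summary of a sharing_fit
#'
#' @param x A `sharing_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `share_fraction`, `auc`, `sigma2`,
#'   `converged`.
#' @export
#' @method glance sharing_fit
glance.sharing_fit <- function(x, ...) {
  tibble::tibble(n = x$n, share_fraction = x$share_fraction,
                 auc = x$auc, sigma2 = x$sigma2, converged = x$converged)
}

#' Tidy a corridor_fit: the Tukey contrast table
#'
#' @param x A `corridor_fit`.
#' @param ... Unused.
#' @return The Tukey tibble (`area_i`, `area_j`, `diff`, `se`, `q`, `p`,
#'   `significant`).
#' @export
#' @method tidy corridor_fit
tidy.corridor_fit <- function(x, ...) x$tukey

#' One-row summary of a corridor_fit
#'
#' @param x A `corridor_fit`.
#' @param ... Unused.
#' @return A tibble with area count, significant-pair count, residual
#'   Moran's I before/after filtering and number of eigenvectors used.
#' @export
#' @method glance corridor_fit
glance.corridor_fit <- function(x, ...) {
  tibble::tibble(
    n_areas = nrow(x$group_stats),
    n_pairs_significant = sum(x$tukey$significant),
    n_pairs = nrow(x$tukey),
    moran_initial = x$filter$moran_initial %||% NA_real_,
    moran_final = x$filter$moran_final %||% NA_real_,
    n_eigenvectors = x$filter$n_selected %||% 0L)
}

#' Tidy sharing_results: the long coefficient table
#'
#' @param x A `sharing_results`.
#' @param ... Unused.
#' @return The `results` tibble.
#' @export
#' @method tidy sharing_results
tidy.sharing_results <- function(x, ...) x$results

#' Per-trait model summary of sharing_results
#'
#' @param x A `sharing_results`.
#' @param ... Unused.
#' @return The `models` tibble.
#' @export
#' @method glance sharing_results
glance.sharing_results <- function(x, ...) x$models
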