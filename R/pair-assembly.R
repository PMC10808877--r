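#' Build society pairs from geodesic nearest neighbours
#'
#' Pairs every society with its `k` geodesic-nearest others (all others when
#' fewer than `k` exist), then de-duplicates on the unordered pair, keeping
#' ids sorted lexicographically. Distance ties are broken by id order.
#'
#' @param societies Society tibble (`id`, `lat`, `lon`).
#' @param k Number of nearest neighbours per society.
#' @return A tibble `id_A`, `id_B` (sorted within pair), `geodesic_km`.
#' @examples
#' soc <- tibble::tibble(id = c("a", "b", "c"), lat = c(0, 1, 2), lon = 0)
#' nearest_pairs(soc, k = 100)
#' @export
nearest_pairs <- function(societies, k = 100) {
  soc <- dplyr::arrange(societies, .data$id)
  n <- nrow(soc)
  if (n < 2) abort("at least two societies are required")
  dm <- geodesic_matrix(soc)
  pairs <- purrr::map(seq_len(n), function(i) {
    ord <- order(dm[i, -i], soc$id[-i])
    nb <- soc$id[-i][ord][seq_len(min(k, n - 1))]
    tibble::tibble(id_A = pmin(soc$id[i], nb), id_B = pmax(soc$id[i], nb))
  })
  dplyr::bind_rows(pairs) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$id_A, .data$id_B) %>%
    dplyr::mutate(geodesic_km = dm[cbind(.data$id_A, .data$id_B)])
}

#' Recode a trait table and drop under-resolved traits
#'
#' Applies an optional code-to-code recoding per trait (e.g. collapsing
#' casual/extensive/intensive agriculture into one agricultural category),
#' then rejects traits whose recoded category count is 2 or fewer: with only
#' two categories, "sharing" carries almost no information. Values equal to
#' `absent_code` are kept but flagged as absent (societies in which the
#' trait is absent never count as sharing); `NA` codes are missing data.
#'
#' @param trait_table Tibble `society_id`, `trait_id`, `code`.
#' @param recoding Optional named list: `recoding[[trait]]` is a named
#'   vector mapping old codes (names) to new codes (values). Codes absent
#'   from the map are left as-is.
#' @param absent_code Optional code value marking trait absence.
#' @return The recoded table with an `absent` logical column and an
#'   attribute `dropped_traits` listing rejected traits.
#' @export
recode_traits <- function(trait_table, recoding = NULL, absent_code = NULL) {
  tt <- dplyr::mutate(trait_table, code = as.character(.data$code))
  if (!is.null(recoding)) {
    for (tr in names(recoding)) {
      map <- recoding[[tr]]
      sel <- tt$trait_id == tr & tt$code %in% names(map)
      tt$code[sel] <- unname(map[tt$code[sel]])
    }
  }
  tt$absent <- if (is.null(absent_code)) FALSE else tt$code %in% as.character(absent_code)
  counts <- tt %>%
    dplyr::filter(!is.na(.data$code), !.data$absent) %>%
    dplyr::group_by(.data$trait_id) %>%
    dplyr::summarise(k = dplyr::n_distinct(.data$code), .groups = "drop")
  dropped <- counts$trait_id[counts$k <= 2]
  if (length(dropped) > 0) {
    inform(sprintf("recode_traits: %d trait(s) with <= 2 categories dropped: %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- dplyr::filter(tt, !(.data$trait_id %in% dropped))
  attr(out, "dropped_traits") <- dropped
  out
}

#' Score cultural sharing for one trait on a pair table
#'
#' A pair shares the trait (flag 1) when both societies carry the same
#' (recoded) code; 0 when the codes differ; `NA` when either side is
#' missing or the trait is flagged absent for either society.
#'
#' @param pairs Pair tibble (`id_A`, `id_B`).
#' @param trait_table A (recoded) trait table; see [recode_traits()].
#' @param trait Trait id to score.
#' @return `pairs` with an added `share` column in `{1, 0, NA}`.
#' @export
score_sharing <- function(pairs, trait_table, trait) {
  tt <- dplyr::filter(trait_table, .data$trait_id == trait)
  if (nrow(tt) == 0) abort(sprintf("unknown trait '%s'", trait))
  code <- setNames(tt$code, tt$society_id)
  absent <- setNames(if ("absent" %in% names(tt)) tt$absent else
    rep(FALSE, nrow(tt)), tt$society_id)
  cA <- code[pairs$id_A]; cB <- code[pairs$id_B]
  bad <- absent[pairs$id_A] | absent[pairs$id_B] |
    is.na(cA) | is.na(cB) |
    !(pairs$id_A %in% names(code)) | !(pairs$id_B %in% names(code))
  bad[is.na(bad)] <- TRUE
  dplyr::mutate(pairs,
                share = dplyr::if_else(bad, NA_integer_,
                                       as.integer(cA == cB)))
}

#' Shared ancestry: patristic (cophenetic) distance between pair members
#'
#' Sum of branch lengths along the path joining the two tips through their
#' most recent common ancestor. Pairs whose tips are missing from the tree
#' are returned with `NA` relatedness and a reason.
#'
#' @param pairs Pair tibble (`id_A`, `id_B`).
#' @param tree A `phylo` with society ids as tip labels.
#' @return `pairs` with `relatedness` (tree units) and `relatedness_reason`
#'   (`NA` or `"tip_missing"`).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
#' relatedness(tibble::tibble(id_A = c("A", "A"), id_B = c("B", "C")), tr)
#' @export
relatedness <- function(pairs, tree) {
  cd <- ape::cophenetic.phylo(tree)
  okA <- pairs$id_A %in% rownames(cd); okB <- pairs$id_B %in% rownames(cd)
  val <- rep(NA_real_, nrow(pairs))
  ok <- okA & okB
  val[ok] <- cd[cbind(pairs$id_A[ok], pairs$id_B[ok])]
  dplyr::mutate(pairs, relatedness = val,
                relatedness_reason = dplyr::if_else(ok, NA_character_,
                                                    "tip_missing"))
}

#' Neighbourhood transmission statistic
#'
#' For a pair (A, B) and a trait, measures the chance each member could
#' have picked the other's value from its own neighbourhood rather than
#' from its pair partner: the fraction of A's nearest neighbours (excluding
#' both A and B) carrying B's code, averaged with the mirror-image fraction
#' for B.
#'
#' Modes: `"five_with_data"` uses, for each side, the 5 nearest societies
#' *with data* for the trait (result `NA` if none exist);
#' `"ten_any"` fixes the 10 nearest societies regardless of data and uses
#' the data-bearing ones as denominator, keeping the pair only when at
#' least 3 of the 10 have data on *both* sides.
#'
#' @param pairs Pair tibble (`id_A`, `id_B`).
#' @param societies Society tibble (`id`, `lat`, `lon`).
#' @param trait_table A (recoded) trait table.
#' @param trait Trait id.
#' @param mode `"five_with_data"` or `"ten_any"`.
#' @return `pairs` with an added `neighbor_trans` column in `[0, 1]` or `NA`.
#' @export
neighbor_transmission <- function(pairs, societies, trait_table, trait,
                                  mode = c("five_with_data", "ten_any")) {
  mode <- match.arg(mode)
  tt <- dplyr::filter(trait_table, .data$trait_id == trait)
  code <- setNames(tt$code, tt$society_id)
  if ("absent" %in% names(tt)) code[tt$society_id[tt$absent]] <- NA
  has_data <- setNames(!is.na(code[societies$id]), societies$id)
  dm <- geodesic_matrix(societies)
  ids <- societies$id

  side <- function(focal, partner) {
    # fraction of focal's neighbours that carry partner's code
    target <- code[[partner]]
    if (is.na(target)) return(NA_real_)
    others <- setdiff(ids, c(focal, partner))
    ord <- others[order(dm[focal, others], others)]
    if (mode == "five_with_data") {
      nb <- head(ord[has_data[ord]], 5)
      if (length(nb) == 0) return(NA_real_)
      mean(code[nb] == target)
    } else {
      nb <- head(ord, 10)
      withd <- nb[has_data[nb]]
      if (length(withd) < 3) return(NA_real_)   # retention rule
      mean(code[withd] == target)
    }
  }
  vals <- purrr::map2_dbl(pairs$id_A, pairs$id_B, function(a, b) {
    sa <- side(a, b); sb <- side(b, a)
    if (is.na(sa) || is.na(sb)) NA_real_ else (sa + sb) / 2
  })
  dplyr::mutate(pairs, neighbor_trans = vals)
}

#' Assemble the full per-trait pair covariate table
#'
#' Joins the sharing flag, the 9 barrier metrics + geodesic distance, the
#' relatedness covariate and the neighbourhood-transmission statistic into
#' the 11-predictor design the sharing models consume, dropping incomplete
#' rows with a count.
#'
#' @param pairs Pair tibble from [nearest_pairs()].
#' @param barriers Barrier table from [pair_barriers()].
#' @param societies,trait_table,tree As elsewhere.
#' @param trait Trait id.
#' @param mode Neighbourhood mode, see [neighbor_transmission()].
#' @return A tibble with `id_A`, `id_B`, `share` and the 11 predictors.
#' @export
assemble_pair_covariates <- function(pairs, barriers, societies, trait_table,
                                     tree, trait,
                                     mode = c("five_with_data", "ten_any")) {
  mode <- match.arg(mode)
  df <- pairs %>%
    dplyr::select("id_A", "id_B") %>%
    dplyr::left_join(dplyr::filter(barriers, !.data$excluded),
                     by = c("id_A", "id_B")) %>%
    score_sharing(trait_table, trait) %>%
    relatedness(tree) %>%
    neighbor_transmission(societies, trait_table, trait, mode = mode)
  preds <- c("th_dissim", "ai_dissim", "th_cost", "th_len", "ai_cost",
             "ai_len", "topo_cost", "topo_len", "geodesic_km",
             "relatedness", "neighbor_trans")
  ok <- complete.cases(df[, c("share", preds)])
  if (any(!ok)) {
    inform(sprintf("assemble_pair_covariates[%s]: %d incomplete pairs dropped",
                   trait, sum(!ok)))
  }
  dplyr::select(df[ok, ], "id_A", "id_B", "share", dplyr::all_of(preds))
}
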