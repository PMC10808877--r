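#' Forest plot of per-trait component effects
#'
#' One point (+/- 1 SE arrow) per trait-by-component coefficient, coloured
#' by the sign of significant effects after FDR adjustment.
#'
#' @param x A `sharing_results` object.
#' @param alpha Significance threshold on the adjusted p-values.
#' @return A ggplot.
#' @export
plot_forest <- function(x, alpha = 0.05) {
  df <- tidy(x) %>%
    dplyr::mutate(
      signif = dplyr::case_when(
        .data$p_adjusted >= alpha ~ "n.s.",
        .data$estimate > 0 ~ "positive",
        TRUE ~ "negative"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$trait,
                                   colour = .data$signif)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - .data$std_error,
                   xmax = .data$estimate + .data$std_error),
      height = 0) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$label, nrow = 1) +
    ggplot2::scale_colour_manual(values = c("n.s." = "grey55",
                                            "negative" = "#2166ac",
                                            "positive" = "#b2182b")) +
    ggplot2::labs(x = "estimated effect (log-odds per component unit)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Moran's I correlogram
#'
#' @param x A `correlogram` from [morans_correlogram()].
#' @param alpha Permutation p threshold for highlighting.
#' @return A ggplot.
#' @export
plot_correlogram <- function(x, alpha = 0.05) {
  df <- dplyr::filter(tibble::as_tibble(x), !.data$degenerate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center_km, y = .data$I)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$p_perm < alpha), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "distance bin center (km)", y = "Moran's I",
                  shape = paste0("p < ", alpha)) +
    ggplot2::theme_minimal()
}

#' Plot area means and SDs of an origin-corridor comparison component
#'
#' @param x A `corridor_fit`.
#' @return A ggplot of mean +/- SD per area, ordered by mean.
#' @export
plot_origin_means <- function(x) {
  df <- dplyr::arrange(x$group_stats, .data$mean) %>%
    dplyr::mutate(area = factor(.data$area, levels = .data$area))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = NULL, y = x$response) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Map an environmental axis
#'
#' @param env An `env_axes` object.
#' @param axis `"TH"` or `"AI"`.
#' @return A ggplot raster map of the axis scores.
#' @export
plot_env_axes <- function(env, axis = c("TH", "AI")) {
  axis <- match.arg(axis)
  ggplot2::ggplot(env$scores,
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               fill = .data[[axis]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = axis) +
    ggplot2::theme_minimal()
}
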