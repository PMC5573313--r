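# ggplot2 helpers for score distributions, ternary compositions and
# conservation profiles.

#' Plot per-class score distributions with threshold lines
#'
#' Tukey boxplots of one predictor's scores per phenotype class, optionally
#' with the calibrated evidence-based threshold and/or the predictor's
#' default threshold overlaid.
#'
#' @param variants Variant tibble with `phenotype` and the score column.
#' @param predictor Score column (tidy evaluation).
#' @param threshold Optional one-row tibble from [evidence_threshold()].
#' @param default_threshold Optional numeric, drawn dashed.
#' @return A ggplot.
#' @export
plot_score_distributions <- function(variants, predictor, threshold = NULL,
                                     default_threshold = NULL) {
  p <- ggplot2::ggplot(
    dplyr::filter(variants, !is.na({{ predictor }})),
    ggplot2::aes(x = .data$phenotype, y = {{ predictor }})) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold$threshold,
                                 colour = "darkgreen")
  }
  if (!is.null(default_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = default_threshold,
                                 colour = "darkblue", linetype = "dashed")
  }
  p
}

#' Ternary plot of harmonized predictor contributions
#'
#' Projects the compositional coordinates from [harmonize_ternary()] onto
#' the plane (equilateral-triangle projection) and colours points by a
#' grouping column.
#'
#' @param data Tibble with `t_ev`, `t_pop`, `t_snap` columns.
#' @param colour Optional grouping column (tidy evaluation).
#' @return A ggplot.
#' @export
plot_ternary <- function(data, colour = NULL) {
  stopifnot(all(c("t_ev", "t_pop", "t_snap") %in% names(data)))
  d <- dplyr::mutate(data,
                     .x = .data$t_pop + .data$t_snap / 2,
                     .y = sqrt(3) / 2 * .data$t_snap)
  tri <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(d, ggplot2::aes(x = .x, y = .y, colour = {{ colour }})) +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5),
                      y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                      label = c("EVmutation", "PoPMuSiC", "SNAP2"), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a conservation profile along the sequence
#'
#' GV per reference position with the conservation cutoff line; optionally
#' overlays per-residue disease-family counts (negated bars below the axis)
#' to visualize the conservation/frequency relationship.
#'
#' @param profile Tibble from [conservation_profile()].
#' @param family_counts Optional tibble with `position`, `families`.
#' @param gv_threshold Cutoff line, Grantham units (default the profile's
#'   own threshold attribute, else 61.3).
#' @return A ggplot.
#' @export
plot_conservation <- function(profile, family_counts = NULL,
                              gv_threshold = NULL) {
  thr <- gv_threshold %||% attr(profile, "gv_threshold") %||% 61.3
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$gv)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::geom_hline(yintercept = thr, colour = "darkgreen") +
    ggplot2::labs(x = "reference position", y = "GV [Grantham units]") +
    ggplot2::theme_minimal()
  if (!is.null(family_counts)) {
    scale <- max(profile$gv, na.rm = TRUE) / max(1, max(family_counts$families))
    p <- p + ggplot2::geom_col(
      data = family_counts,
      ggplot2::aes(x = .data$position, y = -.data$families * scale),
      width = 1, fill = "firebrick", inherit.aes = FALSE)
  }
  p
}
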