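#' Plot split vs full-length homolog tallies per host protein
#'
#' Scatter of `nSplit` against `nFull` (square-root scales), colored by
#' classification; the diagonal separates split-dominant proteins from the
#' rest.
#'
#' @param tallies Tibble from [tally_homologs()].
#' @return A ggplot object.
#' @export
plot_tally <- function(tallies) {
  ggplot2::ggplot(tallies,
                  ggplot2::aes(x = .data$nFull, y = .data$nSplit,
                               colour = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_sqrt() +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "Full-length homologs (genomes)",
                  y = "Split homologs (neighborhoods)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.homology_run <- function(object, ...) plot_tally(object$tallies)

#' @export
autoplot.sensitivity_result <- function(object, ...) {
  counts <- object$grid %>%
    group_by(.data$microbe_cov, .data$human_cov) %>%
    summarise(n_detected = sum(.data$category != "none"), .groups = "drop")
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = factor(.data$microbe_cov),
                               y = factor(.data$human_cov),
                               fill = .data$n_detected)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_detected),
                       colour = "white") +
    ggplot2::labs(x = "Microbe coverage threshold",
                  y = "Human coverage threshold",
                  fill = "Proteins\ndetected") +
    ggplot2::theme_minimal()
}

#' Plot Faith's PD per xenobiotic class
#'
#' @param class_pd Tibble from [rank_classes_by_pd()].
#' @return A ggplot object.
#' @export
plot_class_pd <- function(class_pd) {
  ggplot2::ggplot(class_pd,
                  ggplot2::aes(x = stats::reorder(.data$class_key, .data$pd),
                               y = .data$pd)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Faith's phylogenetic diversity") +
    ggplot2::theme_minimal()
}
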