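# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   geom_vline labs scale_colour_manual theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' Volcano plot of differential accessibility
#'
#' @param object A `diff_access` tibble.
#' @param ... Unused.
#' @return A ggplot: log2 fold-change versus -log10 FDR coloured by class
#'   (Up green, Down red, Stable blue).
#' @export
autoplot.diff_access <- function(object, ...) {
  ggplot(object, aes(
    x = .data$log2_fc, y = -log10(.data$fdr),
    colour = .data$class
  )) +
    geom_point(size = 0.6, alpha = 0.6) +
    scale_colour_manual(values = c(
      Up = "#1b9e4b", Down = "#d7301f",
      Stable = "#3182bd"
    )) +
    labs(
      x = "accessibility log2 fold-change (adult vs P10)",
      y = "-log10 FDR", colour = NULL
    ) +
    theme_minimal()
}

#' Class-fraction bar of Up / Down / Stable sites
#'
#' @param results A classified differential table.
#' @return A ggplot of the three class fractions.
#' @export
plot_class_fractions <- function(results) {
  fr <- class_fractions(results)
  ggplot(fr, aes(x = .data$class, y = .data$fraction, fill = .data$class)) +
    geom_col() +
    scale_colour_manual(values = NULL) +
    ggplot2::scale_fill_manual(values = c(
      Up = "#1b9e4b", Down = "#d7301f",
      Stable = "#3182bd"
    )) +
    labs(x = NULL, y = "fraction of ACS", fill = NULL) +
    theme_minimal()
}

#' Normalised enrichment scores of the top motif sets
#'
#' @param object A `gsea_result` tibble.
#' @param n_top Number of sets to show (by adjusted p-value).
#' @param ... Unused.
#' @return A ggplot NES bar chart.
#' @export
autoplot.gsea_result <- function(object, n_top = 20, ...) {
  top <- head(dplyr::arrange(object, .data$adj_p, .data$p_value), n_top)
  top$set_id <- factor(top$set_id, levels = rev(top$set_id))
  ggplot(top, aes(x = .data$set_id, y = .data$nes, fill = .data$nes > 0)) +
    geom_col(show.legend = FALSE) +
    coord_flip() +
    labs(x = NULL, y = "normalised enrichment score") +
    theme_minimal()
}

#' Motif activities from a penalised fit
#'
#' @param object A `motif_activity` object.
#' @param n_top Number of motifs to show (by absolute activity).
#' @param ... Unused.
#' @return A ggplot bar chart of the strongest activities.
#' @export
autoplot.motif_activity <- function(object, n_top = 20, ...) {
  top <- head(object$activities, n_top)
  top$motif_id <- factor(top$motif_id, levels = rev(top$motif_id))
  ggplot(top, aes(
    x = .data$motif_id, y = .data$activity,
    fill = .data$activity > 0
  )) +
    geom_col(show.legend = FALSE) +
    coord_flip() +
    labs(x = NULL, y = "motif activity (log2FC per match)") +
    theme_minimal()
}

#' Fragment-size distribution plot
#'
#' @param histogram A tibble from [fragment_size_histogram()].
#' @return A ggplot of the fragment-size profile.
#' @export
plot_fragment_sizes <- function(histogram) {
  check_columns(histogram, c("bin_start", "count"), "histogram")
  ggplot(histogram, aes(x = .data$bin_start, y = .data$count)) +
    geom_col(width = diff(range(histogram$bin_start)) /
      max(nrow(histogram) - 1, 1) * 0.9, fill = "#3182bd") +
    labs(x = "fragment size (bp)", y = "fragments") +
    theme_minimal()
}
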