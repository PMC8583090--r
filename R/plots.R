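# ggplot2 views of the main result types.

#' Volcano plot of a disease signature
#'
#' @param object A [build_signature()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.disease_signature <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2FC, -log10(.data$padj),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-object$lfc_cut, object$lfc_cut),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")
    ) +
    ggplot2::labs(title = object$dataset_id, x = "log2 fold change",
                  y = "-log10 adjusted p")
}

#' Ranked sRGES plot
#'
#' Drugs ordered by summarized reversal score, with the selection
#' threshold marked; candidates sit in the lower-left tail.
#'
#' @param srges_tbl Tibble from [summarize_srges()].
#' @param srges_cut Threshold line (default -0.25).
#' @return A ggplot.
#' @export
plot_srges <- function(srges_tbl, srges_cut = -0.25) {
  df <- dplyr::arrange(srges_tbl, .data$srges) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$srges)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_hline(yintercept = srges_cut, linetype = "dashed",
                        colour = "#c0392b") +
    ggplot2::labs(x = "drug rank", y = "sRGES")
}

#' Consensus combined-score heatmap
#'
#' @param object A [build_consensus_list()] result.
#' @param ... Unused.
#' @return A ggplot tile map of log2 combined scores per term and
#'   signature.
#' @export
autoplot.consensus_list <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$signature, .data$term,
                                   fill = log2(pmax(.data$combined, 1)))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2 combined") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Dose-response curves
#'
#' @param curves Tibble `drug`, `cell_line`, `dose_uM`,
#'   `viability_log2fc`.
#' @return A ggplot of viability against log10 dose, one facet per drug.
#' @export
plot_dose_response <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$dose_uM, .data$viability_log2fc,
                                       group = .data$cell_line,
                                       colour = .data$cell_line)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~drug) +
    ggplot2::labs(x = "dose (uM)", y = "viability log2FC")
}

#' Dependency efficacy-selectivity map
#'
#' @param dep_summary Tibble from [dependency_efficacy_selectivity()].
#' @return A ggplot scatter of selectivity against efficacy.
#' @export
plot_dependency <- function(dep_summary) {
  ggplot2::ggplot(dep_summary, ggplot2::aes(.data$efficacy,
                                            .data$selectivity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "efficacy (10th percentile dependency)",
                  y = "selectivity")
}
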