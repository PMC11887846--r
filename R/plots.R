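# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
NULL

#' Volcano plot of a differential result
#'
#' @param object A `differential_result`.
#' @param fdr Highlight threshold (defaults to the stored one).
#' @param ... Ignored.
#' @return A ggplot: log2FC vs -log10 p, faceted by cell type, significant
#'   genes colored.
#' @export
autoplot.differential_result <- function(object, fdr = object$fdr_threshold,
                                         ...) {
  df <- dplyr::mutate(
    object$table,
    significant = !is.na(.data$fdr) & .data$fdr <= fdr
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$log2FC,
                                   -log10(.data$p_value),
                                   color = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  color = sprintf("FDR <= %g", fdr),
                  title = sprintf("%s (%s)", object$contrast,
                                  object$modality)) +
    ggplot2::theme_minimal()
}

#' Covariate balance (Love) plot of a risk-group assignment
#'
#' @param object A `risk_group_assignment`.
#' @param ... Ignored.
#' @return A ggplot of absolute standardized mean differences before and
#'   after matching.
#' @export
autoplot.risk_group_assignment <- function(object, ...) {
  df <- tidyr::pivot_longer(object$balance, c("smd_pre", "smd_post"),
                            names_to = "stage", values_to = "smd") |>
    dplyr::mutate(stage = ifelse(.data$stage == "smd_pre", "before",
                                 "after"))
  ggplot2::ggplot(df, ggplot2::aes(abs(.data$smd), .data$covariate,
                                   color = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  color = "matching",
                  title = sprintf("Covariate balance: %s", object$trait)) +
    ggplot2::theme_minimal()
}

#' Plot a correlation network
#'
#' @param object A `correlation_network`.
#' @param ... Ignored.
#' @return A ggplot of the network with a deterministic circular layout;
#'   edge width encodes |rho|, linetype the sign, node color the modality.
#' @export
autoplot.correlation_network <- function(object, ...) {
  nodes <- object$nodes
  k <- nrow(nodes)
  theta <- 2 * pi * (seq_len(k) - 1) / max(k, 1)
  layout <- tibble::tibble(feature = nodes$feature,
                           x = cos(theta), y = sin(theta),
                           modality = nodes$modality)
  ed <- object$edges |>
    dplyr::left_join(dplyr::select(layout, "feature", x0 = "x", y0 = "y"),
                     by = c(from = "feature")) |>
    dplyr::left_join(dplyr::select(layout, "feature", x1 = "x", y1 = "y"),
                     by = c(to = "feature")) |>
    dplyr::mutate(direction = ifelse(.data$sign > 0, "positive",
                                     "negative"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$weight,
                   linetype = .data$direction),
      color = "grey50", alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(.data$x, .data$y, color = .data$modality), size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), name = "|rho|") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Dot plot of enrichment results
#'
#' @param enrichment Tibble from [pathway_enrichment()] or
#'   [motif_enrichment()].
#' @param max_sets Show at most this many sets (by best FDR).
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment, max_sets = 20) {
  keep <- enrichment |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarize(best = min(.data$fdr), .groups = "drop") |>
    dplyr::arrange(.data$best) |>
    utils::head(max_sets)
  df <- dplyr::semi_join(enrichment, keep, by = "set_id")
  has_ct <- "cell_type" %in% names(df)
  ggplot2::ggplot(df, ggplot2::aes(
    x = if (has_ct) .data$cell_type else .data$direction,
    y = stats::reorder(.data$set_id, -.data$fdr),
    size = .data$overlap_k, color = -log10(.data$fdr)
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = NULL, size = "overlap",
                  color = "-log10 FDR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
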