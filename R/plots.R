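#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a weight-cutoff sweep
#'
#' LR+ against the edge-weight cutoff, dots connected by a dashed line,
#' with the number of surviving predictions mapped to dot size.
#'
#' @param object A `vh_sweep` tibble from [sweep_cutoffs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vh_sweep
#' @export
autoplot.vh_sweep <- function(object, ...) {
  df <- object[is.finite(object$lr_plus), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight_cutoff, y = .data$lr_plus)) +
    ggplot2::geom_line(linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_edges), alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "association weight cutoff", y = "LR+",
                  size = "predictions") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a labelled 2x2 grid
#'
#' @param object A `vh_confusion` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vh_confusion
#' @export
autoplot.vh_confusion <- function(object, ...) {
  df <- tidy(object)
  df$predicted <- ifelse(df$cell %in% c("TP", "FP"), "positive", "negative")
  df$condition <- ifelse(df$cell %in% c("TP", "FN"), "positive", "negative")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$predicted,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$cell, "\n", .data$count))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "condition", y = "prediction") +
    ggplot2::theme_minimal()
}

#' Plot node-level enrichment results
#'
#' One point per (node, taxon) test, -log10 adjusted p against the raw
#' in-clade associated count, significant tests highlighted.
#'
#' @param object A `vh_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vh_enrichment
#' @export
autoplot.vh_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mlq <- -log10(pmax(df$q, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$mlq,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "in-clade associated leaves",
                  y = expression(-log[10]~q), colour = "significant") +
    ggplot2::theme_minimal()
}

#' Heatmap of a group-aggregated network
#'
#' Association counts per (viral family, eukaryote group) pair; positive
#' and negative edges in separate facets.
#'
#' @param agg Output of [aggregate_network()].
#' @return A ggplot.
#' @export
plot_aggregated_network <- function(agg) {
  long <- tidyr::pivot_longer(agg, c("count_positive", "count_negative"),
                              names_to = "sign", names_prefix = "count_",
                              values_to = "n")
  long <- long[long$n > 0, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eukaryote_group,
                                     y = .data$viral_family,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~sign) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "eukaryote group", y = "viral family",
                  fill = "edges") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
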