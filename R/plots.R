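# ggplot2 figures for the main result types.

#' Bar chart of the top nodal redundancy ratios
#'
#' Mirrors the conventional presentation of a ratio set: the `top_n` nodes
#' with the largest between-group ratios, coloured by whether they are
#' target ("posterior hippocampal") nodes.
#'
#' @param object A [ratio_set()] result.
#' @param top_n How many nodes to show (default 20).
#' @param target_nodes Optional node ids highlighted as targets.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.redunet_ratio_set <- function(object, top_n = 20, target_nodes = NULL, ...) {
  cmp <- paste(attr(object, "comparison"), collapse = " : ")
  d <- object |>
    dplyr::filter(!.data$flagged) |>
    dplyr::arrange(.data$rank) |>
    head(top_n) |>
    dplyr::mutate(
      node = factor(.data$node, levels = rev(.data$node)),
      target = .data$node %in% (target_nodes %||% character()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio, y = .data$node,
                                  fill = .data$target)) +
    ggplot2::geom_col(show.legend = !is.null(target_nodes)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#e8735c"),
                               name = "target node") +
    ggplot2::labs(x = sprintf("nodal redundancy ratio (%s)", cmp), y = NULL,
                  title = sprintf("Top %d nodal ratios, %s", top_n, cmp)) +
    ggplot2::theme_minimal()
}

#' Group comparison plot for one ROI metric
#'
#' Box plot of a per-subject metric (e.g. across-density ROI redundancy) by
#' diagnostic group.
#'
#' @param metric_avg Averaged metric tibble ([average_densities()]).
#' @param subjects Subject table with `subject_id` and `group`.
#' @param node Node id to plot.
#' @param metric Metric name (default `"roi_redundancy"`).
#' @return A ggplot object.
#' @export
plot_group_metric <- function(metric_avg, subjects, node,
                              metric = "roi_redundancy") {
  d <- metric_avg |>
    dplyr::filter(.data$metric == !!metric, .data$node == !!node) |>
    dplyr::left_join(subjects[, c("subject_id", "group")], by = "subject_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE, outlier.shape = 21) +
    ggplot2::labs(x = NULL, y = metric, title = node) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for the association suite
#'
#' Standardized betas with nominal significance marks, faceted by outcome
#' and ROI, one point per grouping x method.
#'
#' @param assoc Result tibble from [run_association_suite()].
#' @param alpha Significance threshold used for the shape mark.
#' @return A ggplot object.
#' @export
plot_associations <- function(assoc, alpha = 0.05) {
  ggplot2::ggplot(assoc,
                  ggplot2::aes(x = .data$beta, y = .data$group,
                               colour = .data$method,
                               shape = .data$p_value < alpha)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$outcome),
                        cols = ggplot2::vars(.data$roi)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = sprintf("p < %.2g", alpha)) +
    ggplot2::labs(x = "standardized beta", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
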