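#' Heatmap of per-sample, per-pipeline call counts
#'
#' @param counts Wide count tibble from [count_matrix()].
#' @return A ggplot object (samples on rows, pipelines on columns, fill =
#'   number of calls).
#' @export
plot_count_heatmap <- function(counts) {
  long <- counts %>%
    tidyr::pivot_longer(-"sample_id", names_to = "pipeline_id",
                        values_to = "n_calls")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pipeline_id,
                                     y = .data$sample_id,
                                     fill = .data$n_calls)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "calls", na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Boxplots of a metric by mapper or caller
#'
#' @param metrics Per-unit metrics from [score_metrics()].
#' @param metric Column to plot (`"precision"`, `"recall"`, `"f1"`,
#'   `"n_calls"`).
#' @param by `"mapper"` or `"caller"`.
#' @return A ggplot object; one box per group over per-sample group means.
#' @export
plot_metric_box <- function(metrics, metric = "f1",
                            by = c("mapper", "caller")) {
  by <- match.arg(by)
  agg <- if (by == "mapper") aggregate_by_mapper(metrics) else aggregate_by_caller(metrics)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data[[by]], y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Precision-recall scatter of individual pipelines
#'
#' @param metrics Per-unit metrics from [score_metrics()].
#' @return A ggplot object: one point per (pipeline, sample), colored by
#'   mapper, shaped by caller.
#' @export
plot_precision_recall <- function(metrics) {
  ids <- split_pipeline_id(metrics$pipeline_id)
  d <- dplyr::bind_cols(metrics, ids[c("mapper", "caller")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$recall, y = .data$precision,
                                  colour = .data$mapper,
                                  shape = .data$caller)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pipeline similarity matrix
#'
#' @param object An `snv_similarity`.
#' @param cluster Reorder rows/columns by the clustering leaf order.
#' @param ... Unused.
#' @return A ggplot object with similarity values printed in the cells.
#' @method autoplot snv_similarity
#' @export
autoplot.snv_similarity <- function(object, cluster = TRUE, ...) {
  v <- unclass(object)
  ord <- colnames(v)
  if (cluster && !anyNA(v)) ord <- cluster_pipelines(object)$order
  long <- as_tibble(v, rownames = "pipeline_a") %>%
    tidyr::pivot_longer(-"pipeline_a", names_to = "pipeline_b",
                        values_to = "similarity") %>%
    mutate(pipeline_a = factor(.data$pipeline_a, levels = ord),
           pipeline_b = factor(.data$pipeline_b, levels = rev(ord)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pipeline_a,
                                     y = .data$pipeline_b,
                                     fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$similarity)),
                       size = 2.5) +
    ggplot2::scale_fill_viridis_c(limits = c(min(0, min(v, na.rm = TRUE)), 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0(attr(object, "metric"), " similarity — ",
                                 attr(object, "sample_type") %||% "")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Best F1 versus combination size
#'
#' @param f1_size Output of [f1_by_size()].
#' @return A ggplot object: per-size boxplots of each sample's best F1,
#'   colored by sample type.
#' @export
plot_f1_by_size <- function(f1_size) {
  ggplot2::ggplot(f1_size, ggplot2::aes(x = factor(.data$size),
                                        y = .data$best_f1,
                                        fill = .data$sample_type)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "pipelines in union", y = "best F1",
                  fill = "sample type") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
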