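# ggplot2 views of the result types: per-gene contribution bars for a
# single inference, grouped dot plots of activity scores, and the
# blue-to-red per-sample multi-pathway tile view.

#' Plot per-gene contributions of an activity result
#'
#' Horizontal bars of each target gene's additive log2 contribution to
#' the activity score; positive bars push the call toward active.
#'
#' @param object An `activity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.activity_result <- function(object, ...) {
  df <- tidy(object)
  df$gene <- stats::reorder(df$gene, df$log2_contribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_contribution,
                                   y = .data$gene)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      title = paste0(object$pathway, ": log2odds = ",
                     signif(object$log2odds, 3)),
      x = "log2 contribution", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dot plot of activity scores by group
#'
#' The standard presentation of pathway activity across sample groups:
#' one dot per sample on the log2odds scale, horizontal bar at the group
#' median, optional dashed decision threshold.
#'
#' @param data Tibble with a `log2odds` column (e.g. from
#'   [score_samples()]).
#' @param group Column name (string) holding the grouping variable; when
#'   `NULL` all samples form one group.
#' @param threshold Optional log2odds threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_activity_scores <- function(data, group = NULL, threshold = NULL) {
  stopifnot(is.data.frame(data), "log2odds" %in% names(data))
  df <- data
  df$.group <- if (is.null(group)) "all samples" else as.character(df[[group]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$.group,
                                        y = .data$log2odds)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 1.8,
                         colour = "grey30") +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.4, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "pathway activity score (log2odds)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Heatmap of a multi-pathway per-sample report
#'
#' Tile view of the wide report from [multi_pathway_report()]: one row
#' per sample, one column per pathway, colour-coded log2odds from blue
#' (most inactive) to red (most active).
#'
#' @param report Output of [multi_pathway_report()].
#' @return A ggplot object.
#' @export
plot_pathway_heatmap <- function(report) {
  stopifnot(is.data.frame(report), "sample_id" %in% names(report))
  pathways <- setdiff(names(report), c("sample_id", "qc_pass", "annotation"))
  long <- tidyr::pivot_longer(report[, c("sample_id", pathways)],
                              -"sample_id", names_to = "pathway",
                              values_to = "log2odds")
  long$sample_id <- factor(long$sample_id, levels = rev(report$sample_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pathway, y = .data$sample_id,
                                     fill = .data$log2odds)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "blue3", mid = "white",
                                  high = "red3", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2odds") +
    ggplot2::theme_minimal()
}
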