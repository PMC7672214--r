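#' IFS curve
#'
#' Plots the multiclass MCC against the number of top-ranked features, with
#' the selected optimum marked — the standard way to read an incremental
#' feature selection sweep.
#'
#' @param object an `ifs_result` from [run_ifs()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ifs_result <- function(object, ...) {
  rec <- object$records
  opt <- rec[rec$subset_size == object$optimum_size, ]
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$subset_size, y = .data$mcc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = opt, colour = "red", size = 2.5) +
    ggplot2::labs(
      x = "Number of top-ranked features",
      y = "Multiclass MCC",
      title = paste0("IFS curve (", object$learner, ")"),
      subtitle = paste0("optimum: ", object$optimum_size, " features, MCC ",
                        signif(opt$mcc[1], 3))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a class distribution
#'
#' @param distribution a `class_distribution` from
#'   [summarize_class_distribution()].
#' @return A ggplot bar chart of per-class sample counts.
#' @export
plot_class_distribution <- function(distribution) {
  g <- glance(distribution)
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = stats::reorder(.data$label, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Samples",
                  subtitle = sprintf("%d samples, %d classes, imbalance ratio %.1f",
                                     g$total, g$n_classes, g$imbalance_ratio)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Relevance profile of an mRMR ranking
#'
#' @param object an `mrmr_ranking` from [mrmr_rank()].
#' @param ... unused.
#' @return A ggplot of per-rank relevance and selection score.
#' @export
autoplot.mrmr_ranking <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("score", "relevance"),
                              names_to = "metric", values_to = "nats")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$nats,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Rank", y = "Mutual information (nats)") +
    ggplot2::theme_minimal()
}
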