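#' Plot a hyperparameter sweep
#'
#' Recall, precision, and F-measure against the swept setting (window size or
#' number of trees).
#'
#' @param object A `linker_sweep` tibble from [sweep_window()] or
#'   [sweep_trees()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linker_sweep <- function(object, ...) {
  xvar <- attr(object, "sweep")
  long <- object |>
    tidyr::pivot_longer(c("recall", "precision", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]], y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = if (xvar == "window") "averaging window size (residues)" else "number of trees",
      y = "fold-mean metric", colour = NULL
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-residue linker votes along a sequence
#'
#' The vote-fraction trace with the vote threshold and predicted linker
#' segments shaded; pass the truth segment table to overlay annotations.
#'
#' @param object A `linker_prediction` from [predict_votes()].
#' @param truth_segments Optional tibble (`seq_id`, `start`, `end`) of
#'   annotated linker segments to overlay.
#' @param threshold Vote threshold drawn as a horizontal line (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linker_prediction <- function(object, truth_segments = NULL,
                                       threshold = 0.5, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$vote_fraction))
  seg <- prediction_segments(object)
  if (!is.null(seg) && nrow(seg) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "steelblue", alpha = 0.2
    )
  }
  if (!is.null(truth_segments) && nrow(truth_segments) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = truth_segments,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "darkorange", alpha = 0.15
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$seq_id), scales = "free_x") +
    ggplot2::labs(x = "residue position", y = "fraction of trees voting linker") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a cumulative ablation table
#'
#' F-measure (with recall and precision) after each cumulative group removal.
#'
#' @param object A `linker_ablation` from [ablate_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linker_ablation <- function(object, ...) {
  d <- object
  d$step <- factor(seq_len(nrow(d)),
                   labels = ifelse(d$removed == "none", "none", d$removed))
  long <- tidyr::pivot_longer(d, c("recall", "precision", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     group = .data$metric,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "feature group removed", y = "fold-mean metric",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
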