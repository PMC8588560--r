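# ggplot2 autoplot methods for the package's result types.

#' Plot a recall table
#'
#' Grouped bars of per-class recall by method, with the mean over classes
#' as a dashed reference line per method.
#'
#' @param object A [recall_table].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recall_table <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class_label, y = .data$recall,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "activity class", y = "recall (%)", fill = "method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a pruning sweep
#'
#' Recall as a function of the pruning ratio, one line per activity class —
#' the flat-then-collapse shape is the signature of SNR node pruning.
#'
#' @param object A `prune_sweep` tibble from [prune_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prune_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio, y = .data$recall,
                                       colour = .data$class_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "pruning ratio", y = "recall (%)", colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a concordance result
#'
#' Mean rank per method (higher is better), annotated with W and p.
#'
#' @param object A `concordance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance <- function(object, ...) {
  mr <- object$mean_ranks
  mr$method <- factor(mr$method, levels = rev(mr$method))
  ggplot2::ggplot(mr, ggplot2::aes(x = .data$mean_rank, y = .data$method)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "mean rank", y = NULL,
      title = sprintf("Kendall W = %.3f, p = %.2g", object$W, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Training (and validation, if recorded) binary cross-entropy per epoch.
#'
#' @param object A `siamese_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.siamese_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "loss")
  h <- h[!is.na(h$loss), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}
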