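#' ROC curve points
#'
#' True- and false-positive rates at every score cutoff, suitable for a ROC
#' plot; the staircase starts at (0, 0) and ends at (1, 1).
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  check_two_classes(labels, scores)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == 1)
  fp <- cumsum(labels[o] == 0)
  # collapse ties so each distinct score contributes one point
  last_of_tie <- c(diff(scores[o]) != 0, TRUE)
  tibble(
    fpr = c(0, fp[last_of_tie] / sum(labels == 0)),
    tpr = c(0, tp[last_of_tie] / sum(labels == 1))
  )
}

#' Q-Q plot of association p-values
#'
#' Observed versus expected `-log10` p-value quantiles with the identity
#' line; systematic departure from the diagonal is the visual counterpart of
#' a genomic inflation factor away from 1.
#'
#' @param p p-values in `(0, 1]` (or an `assoc_result` tibble).
#' @return A ggplot object.
#' @export
plot_qq <- function(p) {
  if (is.data.frame(p)) p <- p$p[p$converged]
  pts <- qq_points(p)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p))
    ) +
    ggplot2::theme_minimal()
}

#' ROC curves per channel
#'
#' Plots each channel's test-fold ROC at its selected cutoff, pooling test
#' folds (every sample is scored exactly once at the selected cutoff).
#'
#' @param eval a `channel_eval` object.
#' @return A ggplot object.
#' @export
plot_roc <- function(eval) {
  stopifnot(inherits(eval, "channel_eval"))
  curves <- purrr::imap(eval$cv, function(cv, ch) {
    rows <- cv$scores |>
      filter(.data$threshold == cv$best_threshold)
    lab <- cv$labels[match(rows$sample_id, cv$sample_ids)]
    roc_points(rows$prs, lab) |> mutate(channel = ch)
  }) |> bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$channel)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @param object,... `autoplot()` method arguments.
#' @export
autoplot.channel_eval <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(
    x = stats::reorder(.data$channel, -.data$auc),
    y = .data$auc
  )) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$auc - .data$auc_sd,
        ymax = .data$auc + .data$auc_sd
      ),
      width = 0.15
    ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0.4, NA)) +
    ggplot2::labs(x = NULL, y = "Fold-mean AUC (± SD)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @export
autoplot.cv_prs <- function(object, ...) {
  cells <- object$cells |> filter(.data$usable)
  ggplot2::ggplot(cells, ggplot2::aes(
    x = .data$threshold, y = .data$auc,
    group = .data$fold
  )) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_vline(
      xintercept = object$best_threshold,
      colour = "firebrick", linetype = "dotted"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "p-value cutoff", y = "Test-fold AUC") +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @export
autoplot.overlap_report <- function(object, ...) {
  pc <- object$per_channel |> mutate(order = factor(.data$order))
  ggplot2::ggplot(pc, ggplot2::aes(
    x = .data$channel, y = .data$pct,
    fill = .data$order
  )) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(
      x = NULL, y = "% of channel's positive labels",
      fill = "Overlap order"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
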