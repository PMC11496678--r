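#' Box plots of the per-case index medians by TR grade
#'
#' @param indices a `cvp_indices` object.
#' @return a ggplot object (three facets, one per index).
#' @export
plot_index_boxplots <- function(indices) {
  stopifnot(inherits(indices, "cvp_indices"))
  long <- tidyr::pivot_longer(indices$cases,
                              cols = c("v_minus_y", "x_minus_y", "c_minus_y"),
                              names_to = "index", values_to = "mmHg")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tr_grade, y = .data$mmHg)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "TR grade", y = "pressure difference (mmHg)") +
    ggplot2::theme_minimal()
}

#' Empirical ROC curve with the Youden cutoff marked
#'
#' @param roc a `roc_result` from [roc_analysis()].
#' @return a ggplot object.
#' @export
plot_roc <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  pts <- roc$points[order(1 - roc$points$specificity, roc$points$sensitivity), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::annotate("point", x = 1 - roc$specificity, y = roc$sensitivity,
                      colour = "red", size = 2) +
    ggplot2::labs(
      title = sprintf("AUC %.2f (95%% CI %.2f-%.2f), cutoff %.1f mmHg",
                      roc$auc, roc$ci[1], roc$ci[2], roc$cutoff),
      x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Mean attention-rollout saliency over a set of beats
#'
#' @param saliency matrix from [explain_beats()].
#' @return a ggplot object of the positionwise mean saliency.
#' @export
plot_saliency <- function(saliency) {
  df <- tibble::tibble(position = seq_len(ncol(saliency)),
                       saliency = colMeans(saliency))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$saliency)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "beat position (of resampled length)",
                  y = "mean rollout saliency") +
    ggplot2::theme_minimal()
}
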