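# ggplot2 views of the pipeline's result tables.

#' Boxplot of ROI x condition synchrony indexes
#'
#' One box per condition, facetted by ROI. Remember the direction convention:
#' a larger normalized distance means lower interpersonal synchrony.
#'
#' @param roi_index Tibble from [aggregate_roi_condition()].
#' @return A ggplot.
#' @export
plot_roi_condition <- function(roi_index) {
  assert_columns(roi_index, c("roi", "condition", "index"), "`roi_index`")
  roi_index |>
    dplyr::mutate(condition = factor(.data$condition,
                                     c("positive", "negative", "baseline"))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$condition, y = .data$index)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.5) +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = NULL, y = "normalized DTW distance",
                  title = "Dyadic synchrony by condition",
                  subtitle = "larger distance = lower synchrony") +
    ggplot2::theme_minimal()
}

#' Scatterplot of satisfaction difference against the synchrony index
#'
#' Per-dyad emotion-averaged index of one cluster against the dyad's
#' satisfaction difference, with the OLS line — the view behind the
#' pipeline's Pearson correlation.
#'
#' @param roi_index Tibble from [aggregate_roi_condition()] joined with
#'   `delta_sat`.
#' @param cluster Which ROI to display.
#' @return A ggplot.
#' @export
plot_satisfaction_synchrony <- function(roi_index, cluster = "frontal_right") {
  assert_columns(roi_index, c("dyad_id", "roi", "condition", "index",
                              "delta_sat"), "`roi_index`")
  per_dyad <- roi_index |>
    dplyr::filter(.data$roi == cluster,
                  .data$condition %in% c("positive", "negative")) |>
    dplyr::group_by(.data$dyad_id, .data$delta_sat) |>
    dplyr::summarise(index = mean(.data$index), .groups = "drop")
  ggplot2::ggplot(per_dyad,
                  ggplot2::aes(x = .data$delta_sat, y = .data$index)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = "relationship satisfaction difference",
                  y = "mean normalized DTW distance",
                  title = sprintf("Satisfaction difference vs. synchrony (%s)",
                                  cluster)) +
    ggplot2::theme_minimal()
}
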