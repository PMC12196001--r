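# Dynamic Time Warping with the normalized distance index.
#
# The synchrony metric of the pipeline: the minimum cumulative |x_i - y_j|
# cost over monotone warping paths under the symmetric2 step pattern
# (diagonal moves weighted twice), divided by N + M, the combined length of
# the two series. Identical series score 0; larger index = lower synchrony.

#' Align two series by Dynamic Time Warping (symmetric2)
#'
#' Computes the optimal monotone alignment between `x` and `y` under the
#' symmetric2 step pattern with local cost `|x_i - y_j|`, and the normalized
#' distance index `total / (N + M)` — the symmetric2 pattern's standard
#' normalization by the combined length of the two series. An optional
#' Sakoe-Chiba band restricts the warping to `|i - j| <= window`.
#'
#' @param x,y Non-empty finite numeric series.
#' @param window Optional Sakoe-Chiba band half-width in samples
#'   (`NULL` = unconstrained).
#' @param keep_path If `TRUE`, the optimal warping path is recovered by
#'   backtracking (diagonal preferred on ties).
#' @return A `dtw_alignment` object with `total_distance`,
#'   `normalized_distance`, series lengths `n`, `m`, the `step_pattern`
#'   identifier, `window`, and (if requested) the `path` tibble of index
#'   pairs.
#' @export
#' @examples
#' dtw_align(c(0, 0), c(1, 1))$normalized_distance # 0.75
dtw_align <- function(x, y, window = NULL, keep_path = TRUE) {
  if (length(x) == 0L || length(y) == 0L) {
    abort("Both series must be non-empty.", class = "dyadsync_parameter_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Both series must be finite.", class = "dyadsync_parameter_error")
  }
  band <- if (is.null(window)) -1L else as.integer(window)
  res <- dtw_cpp(as.numeric(x), as.numeric(y), band = band,
                 keep_path = keep_path)
  if (!res$feasible) {
    abort("No warping path exists under this window constraint.",
          class = "dyadsync_infeasible_window_error")
  }
  structure(list(
    total_distance = res$total,
    normalized_distance = res$total / (length(x) + length(y)),
    n = length(x), m = length(y),
    step_pattern = "symmetric2",
    window = window,
    path = if (keep_path) {
      tibble::tibble(i = res$path_i, j = res$path_j)
    } else NULL
  ), class = "dtw_alignment")
}

#' Normalized DTW distance between two series
#'
#' Distance-only fast path of [dtw_align()] (no path backtracking).
#'
#' @inheritParams dtw_align
#' @return The normalized distance `total / (N + M)`.
#' @export
dtw_distance <- function(x, y, window = NULL) {
  dtw_align(x, y, window = window, keep_path = FALSE)$normalized_distance
}

#' Per-channel normalized DTW distances between two subjects' segments
#'
#' Takes a long data frame of paired segments and returns one normalized
#' distance per channel common to both subjects; channels present in only
#' one subject are absent from the output (missing, never zero).
#'
#' @param segments A data frame with columns `subject` (two levels),
#'   `channel`, `sample_index` and a value column.
#' @param value Name of the value column (default `"value"`).
#' @param window Optional Sakoe-Chiba band half-width.
#' @return A tibble (channel, normalized_distance), sorted by channel. Warns
#'   (`dyadsync_empty_result`) and returns zero rows if the subjects share no
#'   channel.
#' @export
normalized_distance_by_channel <- function(segments, value = "value",
                                           window = NULL) {
  assert_columns(segments, c("subject", "channel", "sample_index", value),
                 "`segments`")
  subjects <- sort(unique(segments$subject))
  if (length(subjects) != 2L) {
    abort("`segments` must contain exactly two subjects.",
          class = "dyadsync_dyad_completeness_error")
  }
  by_subject <- split(segments, segments$subject)
  common <- intersect(unique(by_subject[[1]]$channel),
                      unique(by_subject[[2]]$channel))
  if (length(common) == 0L) {
    warning(warningCondition("No channel retained in both subjects.",
                             class = "dyadsync_empty_result"))
    return(tibble::tibble(channel = integer(), normalized_distance = double()))
  }
  pull_channel <- function(d, ch) {
    d <- d[d$channel == ch, ]
    d[[value]][order(d$sample_index)]
  }
  tibble::tibble(
    channel = sort(common),
    normalized_distance = vapply(sort(common), function(ch) {
      dtw_distance(pull_channel(by_subject[[1]], ch),
                   pull_channel(by_subject[[2]], ch), window = window)
    }, numeric(1))
  )
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf(
    "<dtw_alignment> %d x %d, %s, total %.6g, normalized %.6g\n",
    x$n, x$m, x$step_pattern, x$total_distance, x$normalized_distance))
  invisible(x)
}

#' @rdname dtw_align
#' @param x A `dtw_alignment`.
#' @param ... Unused.
#' @method tidy dtw_alignment
#' @export
tidy.dtw_alignment <- function(x, ...) {
  if (is.null(x$path)) {
    abort("Alignment was computed with `keep_path = FALSE`.",
          class = "dyadsync_parameter_error")
  }
  x$path
}

#' @rdname dtw_align
#' @method glance dtw_alignment
#' @export
glance.dtw_alignment <- function(x, ...) {
  tibble::tibble(total_distance = x$total_distance,
                 normalized_distance = x$normalized_distance,
                 n = x$n, m = x$m, step_pattern = x$step_pattern,
                 window = x$window %||% NA_integer_,
                 path_length = if (is.null(x$path)) NA_integer_ else nrow(x$path))
}

#' Plot a DTW warping path
#'
#' @param object A `dtw_alignment` computed with `keep_path = TRUE`.
#' @param ... Unused.
#' @return A ggplot of the warping path over the alignment grid.
#' @method autoplot dtw_alignment
#' @export
autoplot.dtw_alignment <- function(object, ...) {
  path <- tidy(object)
  ggplot2::ggplot(path, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_abline(slope = object$m / object$n, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::coord_fixed(ratio = object$n / object$m) +
    ggplot2::labs(x = "index in x", y = "index in y",
                  title = sprintf("DTW path (normalized distance %.4g)",
                                  object$normalized_distance)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
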