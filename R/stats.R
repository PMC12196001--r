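# The study's three analyses on the ROI x condition indexes:
#  - Kruskal-Wallis across positive / negative / baseline (and the 2-group
#    emotion-vs-baseline variant, which is the same operation with 2 groups);
#  - per-ROI OLS: index ~ satisfaction difference + emotion dummy
#    (positive = 1), positive and negative conditions only;
#  - Pearson correlation between satisfaction difference and the
#    emotion-averaged right-cluster index.
# The Kruskal-Wallis treats the three condition samples as independent even
# though they are repeated measures on the same dyads; that replicates the
# original analysis and is flagged in the documentation.

#' Kruskal-Wallis rank test (tidy wrapper)
#'
#' Mid-rank statistic with tie correction,
#' `H = [12 / (N(N+1))] * sum(R_j^2 / n_j) - 3(N+1)` divided by
#' `1 - sum(t^3 - t) / (N^3 - N)`, with `df = groups - 1` and the p-value
#' from the chi-square upper tail. If every pooled value is identical the
#' tie correction degenerates; `H = 0` is returned with a warning.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping variable.
#' @return A one-row tibble (statistic, df, p.value, n, n_groups).
#' @export
#' @examples
#' kruskal_wallis(data.frame(y = c(1, 2, 3, 4), g = c("a", "a", "b", "b")),
#'                "y", "g")
kruskal_wallis <- function(data, value = "index", group = "condition") {
  assert_columns(data, c(value, group), "`data`")
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L || any(tabulate(g) == 0L)) {
    abort("Need at least 2 non-empty groups.",
          class = "dyadsync_parameter_error")
  }
  if (length(unique(y)) == 1L) {
    warning(warningCondition(
      "All pooled values identical: tie correction degenerate, H = 0.",
      class = "dyadsync_degenerate_ties"))
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L,
                          p.value = 1, n = length(y), n_groups = nlevels(g)))
  }
  kt <- kruskal.test(y, g)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p.value = kt$p.value,
                 n = length(y), n_groups = nlevels(g))
}

#' Build the regression input from a ROI x condition index table
#'
#' Keeps the positive and negative conditions (the baseline block is
#' excluded from the regression), codes the emotion dummy as positive = 1,
#' negative = 0, and restricts to one ROI. With a complete 15-dyad cohort
#' this yields 30 rows per ROI and residual df 27 for the 3-coefficient
#' model.
#'
#' @param roi_index A tibble from [aggregate_roi_condition()] +
#'   [join_dyad_metadata()] (columns dyad_id, roi, condition, index,
#'   delta_sat).
#' @param roi Which ROI to keep.
#' @return A tibble (dyad_id, roi, condition, index, satisfaction_difference,
#'   emotion_positive).
#' @export
regression_input <- function(roi_index, roi = "frontal_right") {
  assert_columns(roi_index, c("dyad_id", "roi", "condition", "index",
                              "delta_sat"), "`roi_index`")
  roi_index |>
    dplyr::filter(.data$roi == !!roi,
                  .data$condition %in% c("positive", "negative")) |>
    dplyr::transmute(.data$dyad_id, .data$roi, .data$condition,
                     .data$index,
                     satisfaction_difference = .data$delta_sat,
                     emotion_positive = as.integer(.data$condition == "positive"))
}

#' Ordinary least squares for the distance-index model
#'
#' Fits `index ~ satisfaction_difference + emotion_positive` by OLS. The
#' satisfaction-difference coefficient is the quantity of interest: a
#' negative estimate means dyads with more mismatched satisfaction show a
#' lower normalized distance, i.e. greater neural synchrony.
#'
#' @param input A tibble from [regression_input()] (needs columns `index`,
#'   `satisfaction_difference`, `emotion_positive`).
#' @return A `distance_regression` object (wrapping the `lm` fit) with
#'   [tidy()] and [glance()] methods.
#' @export
fit_distance_regression <- function(input) {
  assert_columns(input, c("index", "satisfaction_difference",
                          "emotion_positive"), "`input`")
  if (nrow(input) < 4L) {
    abort("Need at least 4 rows to fit the 3-coefficient model.",
          class = "dyadsync_parameter_error")
  }
  fit <- lm(index ~ satisfaction_difference + emotion_positive, data = input)
  if (fit$rank < 3L) {
    abort("Design matrix is rank deficient (collinear predictors).",
          class = "dyadsync_collinearity_error")
  }
  structure(list(fit = fit, n = nrow(input)), class = "distance_regression")
}

#' @rdname fit_distance_regression
#' @param x,object A `distance_regression`.
#' @param ... Unused.
#' @method tidy distance_regression
#' @export
tidy.distance_regression <- function(x, ...) {
  s <- unname(summary(x$fit)$coefficients)
  tibble::tibble(term = rownames(summary(x$fit)$coefficients),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_distance_regression
#' @method glance distance_regression
#' @export
glance.distance_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 df.residual = x$fit$df.residual, nobs = x$n)
}

#' @export
print.distance_regression <- function(x, ...) {
  cat("<distance_regression> index ~ satisfaction_difference + emotion_positive\n")
  print(tidy(x))
  cat(sprintf("residual df: %d\n", x$fit$df.residual))
  invisible(x)
}

#' Pearson correlation (tidy wrapper)
#'
#' Sample correlation with the two-tailed p-value from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @return A one-row tibble (estimate, statistic, p.value, n).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must have equal length n >= 3.",
          class = "dyadsync_parameter_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined for constant input.",
          class = "dyadsync_undefined_correlation_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 p.value = ct$p.value, n = length(x))
}

#' Run the study's statistical battery on a ROI x condition table
#'
#' Computes, on the chosen cluster: the 3-group Kruskal-Wallis across
#' positive / negative / baseline per-dyad indexes; the 2-group variant
#' comparing the emotion conditions (per-dyad mean of positive and negative)
#' with baseline; per-ROI OLS of index on satisfaction difference and the
#' positive-emotion dummy (both clusters always reported); and the Pearson
#' correlation between satisfaction difference and the per-dyad
#' emotion-averaged index of the chosen cluster.
#'
#' @param roi_index Tibble from [aggregate_roi_condition()] joined with
#'   dyad metadata (`delta_sat`).
#' @param cluster ROI whose indexes enter the Kruskal-Wallis and Pearson
#'   analyses (default `"frontal_right"`).
#' @return A `synchrony_stats` object: tibbles `kw_three_way`, `kw_two_way`,
#'   `pearson`, a named list `regression` (one `distance_regression` per
#'   ROI), and the options used.
#' @export
synchrony_stats <- function(roi_index, cluster = "frontal_right") {
  assert_columns(roi_index, c("dyad_id", "roi", "condition", "index",
                              "delta_sat"), "`roi_index`")
  clus <- roi_index |> dplyr::filter(.data$roi == cluster)
  if (nrow(clus) == 0L) {
    abort(sprintf("No rows for cluster \"%s\".", cluster),
          class = "dyadsync_empty_result")
  }
  kw3 <- kruskal_wallis(clus, "index", "condition")

  per_dyad <- clus |>
    dplyr::group_by(.data$dyad_id, .data$delta_sat) |>
    dplyr::summarise(
      emotion = mean(.data$index[.data$condition %in% c("positive", "negative")]),
      baseline = mean(.data$index[.data$condition == "baseline"]),
      .groups = "drop")
  two <- tidyr::pivot_longer(per_dyad, c("emotion", "baseline"),
                             names_to = "condition", values_to = "index") |>
    dplyr::filter(is.finite(.data$index))
  kw2 <- kruskal_wallis(two, "index", "condition")

  rois <- sort(unique(roi_index$roi))
  regression <- lapply(setNames(rois, rois), function(r) {
    fit_distance_regression(regression_input(roi_index, roi = r))
  })

  ok <- is.finite(per_dyad$emotion)
  pearson <- pearson_corr(per_dyad$delta_sat[ok], per_dyad$emotion[ok])

  structure(list(kw_three_way = kw3, kw_two_way = kw2,
                 regression = regression, pearson = pearson,
                 options = list(cluster = cluster,
                                emotion_dummy = "positive = 1",
                                conditions_in_regression = c("positive", "negative"))),
            class = "synchrony_stats")
}

#' @rdname synchrony_stats
#' @param x,object A `synchrony_stats` object.
#' @param ... Unused.
#' @method tidy synchrony_stats
#' @export
tidy.synchrony_stats <- function(x, ...) {
  dplyr::bind_rows(
    x$kw_three_way |>
      dplyr::transmute(analysis = "kruskal_wallis_3way", term = "H",
                       estimate = .data$statistic, df = as.numeric(.data$df),
                       p.value = .data$p.value),
    x$kw_two_way |>
      dplyr::transmute(analysis = "kruskal_wallis_2way", term = "H",
                       estimate = .data$statistic, df = as.numeric(.data$df),
                       p.value = .data$p.value),
    purrr::imap_dfr(x$regression, function(fit, roi) {
      tidy(fit) |>
        dplyr::mutate(analysis = paste0("regression_", roi),
                      df = fit$fit$df.residual, .before = 1L) |>
        dplyr::select("analysis", "term", "estimate", "df", "p.value")
    }),
    x$pearson |>
      dplyr::transmute(analysis = "pearson", term = "r",
                       estimate = .data$estimate,
                       df = as.numeric(.data$n - 2), p.value = .data$p.value)
  )
}

#' @rdname synchrony_stats
#' @method glance synchrony_stats
#' @export
glance.synchrony_stats <- function(x, ...) {
  right <- x$regression[[x$options$cluster]]
  sat_term <- tidy(right) |>
    dplyr::filter(.data$term == "satisfaction_difference")
  tibble::tibble(
    kw3_H = x$kw_three_way$statistic, kw3_p = x$kw_three_way$p.value,
    kw2_H = x$kw_two_way$statistic, kw2_p = x$kw_two_way$p.value,
    slope = sat_term$estimate, slope_se = sat_term$std.error,
    slope_p = sat_term$p.value,
    df_residual = right$fit$df.residual,
    pearson_r = x$pearson$estimate, pearson_p = x$pearson$p.value,
    n_dyads = x$pearson$n
  )
}

#' @export
print.synchrony_stats <- function(x, ...) {
  cat(sprintf("<synchrony_stats> cluster: %s\n", x$options$cluster))
  cat(sprintf("Kruskal-Wallis 3-way: H(%d, n = %d) = %.3f, p = %.3f\n",
              x$kw_three_way$df, x$kw_three_way$n / x$kw_three_way$n_groups,
              x$kw_three_way$statistic, x$kw_three_way$p.value))
  cat(sprintf("Kruskal-Wallis 2-way: H(%d) = %.3f, p = %.3f\n",
              x$kw_two_way$df, x$kw_two_way$statistic, x$kw_two_way$p.value))
  for (r in names(x$regression)) {
    sl <- tidy(x$regression[[r]]) |>
      dplyr::filter(.data$term == "satisfaction_difference")
    cat(sprintf("%s slope: %.3g (t(%d) = %.2f, p = %.3f)\n", r, sl$estimate,
                x$regression[[r]]$fit$df.residual, sl$statistic, sl$p.value))
  }
  cat(sprintf("Pearson (right cluster): r = %.3f, p = %.3f, n = %d\n",
              x$pearson$estimate, x$pearson$p.value, x$pearson$n))
  invisible(x)
}
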