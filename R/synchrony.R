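# Per-block synchrony and ROI aggregation.
#
# Each 114 s video block is aligned separately per channel; block indexes are
# then averaged channels -> ROI first, then blocks -> condition (mean of
# means). The baseline condition is the neutral ocean video block, not the
# fixation periods.

#' Channel-to-ROI lookup for the ventral prefrontal montage
#'
#' The 8 analysis channels partition into two regions of interest:
#' frontal left `{4, 6, 7, 11}` and frontal right `{13, 14, 16, 19}`,
#' covering the ventrolateral PFC (channels 4/19), ventromedial PFC (7/14)
#' and orbitofrontal cortex (6/11 left, 13/16 right).
#'
#' @return A tibble (channel, roi, subregion).
#' @export
channel_roi_map <- function() {
  tibble::tibble(
    channel = c(4L, 6L, 7L, 11L, 13L, 14L, 16L, 19L),
    roi = rep(c("frontal_left", "frontal_right"), each = 4L),
    subregion = c("VLPFC_L", "OFC_L", "VMPFC_L", "OFC_L",
                  "OFC_R", "VMPFC_R", "OFC_R", "VLPFC_R")
  )
}

#' Cut a preprocessed recording into video-block segments
#'
#' Each video block maps to the half-open sample window
#' `[floor(onset * fs), floor(onset * fs) + floor(114 * fs))` (0-based,
#' floor-aligned, so adjacent blocks never overlap). Fixation periods are not
#' segmented.
#'
#' @param hemo A `hemo_series` from [preprocess_dyad()].
#' @param schedule A schedule tibble from [make_schedule()]; defaults to the
#'   recording's own sequence.
#' @param signal Which concentration series to segment: `"hbo"` (default),
#'   `"hbr"`, or `"mean"` (average of HbO and sign-flipped HbR).
#' @return A tibble (subject, channel, block, condition, sample_index,
#'   value) with `block` numbering the videos 1..7 in presentation order.
#' @export
segment_blocks <- function(hemo, schedule = NULL, signal = c("hbo", "hbr", "mean")) {
  signal <- match.arg(signal)
  schedule <- schedule %||% make_schedule(hemo$sequence_label)
  fs <- hemo$sampling_rate
  n <- max(hemo$hemo$sample_index) + 1L
  videos <- schedule[schedule$is_video, ]
  starts <- floor(videos$onset * fs)
  lens <- floor(videos$duration * fs)
  over <- starts + lens > n
  if (any(over)) {
    abort(sprintf("Schedule overruns the series at block \"%s\" (needs %d samples, have %d).",
                  videos$condition[which(over)[1]],
                  max(starts + lens), n),
          class = "dyadsync_truncation_error")
  }
  value <- switch(signal,
                  hbo = hemo$hemo$hbo,
                  hbr = hemo$hemo$hbr,
                  mean = (hemo$hemo$hbo - hemo$hemo$hbr) / 2)
  base <- hemo$hemo |>
    dplyr::mutate(value = value) |>
    dplyr::select("subject", "channel", "sample_index", "value")
  purrr::map_dfr(seq_len(nrow(videos)), function(b) {
    base |>
      dplyr::filter(.data$sample_index >= starts[b],
                    .data$sample_index < starts[b] + lens[b]) |>
      dplyr::mutate(block = b, condition = videos$condition[b],
                    .before = "sample_index")
  })
}

#' Per-channel per-block synchrony table for one dyad
#'
#' For every channel retained in both subjects and every video block, the
#' normalized DTW distance between the two partners' segments. Channels lost
#' in either subject are simply absent (missing, never zero-filled).
#'
#' @param hemo A `hemo_series` holding both subjects.
#' @param schedule Optional schedule override (defaults to the recording's
#'   sequence).
#' @param signal Concentration series entering DTW (see [segment_blocks()]).
#' @param window Optional Sakoe-Chiba band half-width in samples.
#' @return A tibble (dyad_id, channel, block, condition,
#'   normalized_distance). Zero rows (with a `dyadsync_empty_result`
#'   warning) if no channel is common.
#' @export
compute_dyad_synchrony <- function(hemo, schedule = NULL,
                                   signal = "hbo", window = NULL) {
  schedule <- schedule %||% make_schedule(hemo$sequence_label)
  fs <- hemo$sampling_rate
  h <- hemo$hemo
  n <- max(h$sample_index) + 1L
  videos <- schedule[schedule$is_video, ]
  starts <- floor(videos$onset * fs)
  lens <- floor(videos$duration * fs)
  if (any(starts + lens > n)) {
    abort(sprintf("Schedule overruns the series at block \"%s\".",
                  videos$condition[which(starts + lens > n)[1]]),
          class = "dyadsync_truncation_error")
  }
  sig <- switch(match.arg(signal, c("hbo", "hbr", "mean")),
                hbo = h$hbo, hbr = h$hbr, mean = (h$hbo - h$hbr) / 2)
  key <- paste(h$subject, h$channel)
  vecs <- split(sig, factor(key, unique(key)))
  common <- sort(intersect(unique(h$channel[h$subject == "a"]),
                           unique(h$channel[h$subject == "b"])))
  if (length(common) == 0L) {
    warning(warningCondition("No channel retained in both subjects.",
                             class = "dyadsync_empty_result"))
    return(tibble::tibble(dyad_id = character(), channel = integer(),
                          block = integer(), condition = character(),
                          normalized_distance = double()))
  }
  n_blocks <- nrow(videos)
  dist <- matrix(NA_real_, length(common), n_blocks)
  for (ci in seq_along(common)) {
    xa <- vecs[[paste("a", common[ci])]]
    xb <- vecs[[paste("b", common[ci])]]
    for (b in seq_len(n_blocks)) {
      idx <- (starts[b] + 1L):(starts[b] + lens[b])
      dist[ci, b] <- dtw_distance(xa[idx], xb[idx], window = window)
    }
  }
  tibble::tibble(
    dyad_id = hemo$dyad_id,
    channel = rep(common, each = n_blocks),
    block = rep(seq_len(n_blocks), length(common)),
    condition = rep(videos$condition, length(common)),
    normalized_distance = as.vector(t(dist))
  )
}

#' Synchrony tables for a whole cohort
#'
#' @param hemo_list List of `hemo_series` objects (one per dyad).
#' @param signal,window Passed to [compute_dyad_synchrony()].
#' @return The row-bound synchrony tibble across dyads.
#' @export
cohort_synchrony <- function(hemo_list, signal = "hbo", window = NULL) {
  purrr::map_dfr(hemo_list, compute_dyad_synchrony, signal = signal,
                 window = window)
}

#' Aggregate a synchrony table to ROI x condition indexes
#'
#' Unweighted mean over the available channels within each ROI per block,
#' then mean over blocks within each valence condition (positive = happiness,
#' love, pride; negative = sadness, fear, disgust; baseline = the neutral
#' video). A (dyad, ROI) cell with no retained channel is missing from the
#' output, not zero.
#'
#' @param sync_table A synchrony tibble from [compute_dyad_synchrony()] or
#'   [cohort_synchrony()].
#' @param roi_map A channel-to-ROI tibble (default [channel_roi_map()]).
#' @return A tibble (dyad_id, roi, condition, index, n_channels_used) with
#'   `condition` in positive/negative/baseline.
#' @export
aggregate_roi_condition <- function(sync_table, roi_map = channel_roi_map()) {
  assert_columns(sync_table,
                 c("dyad_id", "channel", "block", "condition",
                   "normalized_distance"), "`sync_table`")
  if (nrow(sync_table) == 0L) {
    abort("Synchrony table is empty.", class = "dyadsync_empty_result")
  }
  sync_table |>
    dplyr::inner_join(roi_map[c("channel", "roi")], by = "channel") |>
    dplyr::mutate(valence = condition_valence(.data$condition)) |>
    dplyr::group_by(.data$dyad_id, .data$roi, .data$valence, .data$block) |>
    dplyr::summarise(block_index = mean(.data$normalized_distance),
                     n_channels = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$dyad_id, .data$roi, condition = .data$valence) |>
    dplyr::summarise(index = mean(.data$block_index),
                     n_channels_used = min(.data$n_channels),
                     .groups = "drop")
}

#' Attach dyad metadata to a ROI x condition index table
#'
#' @param roi_index Output of [aggregate_roi_condition()].
#' @param manifest A cohort manifest tibble with `dyad_id` and `delta_sat`.
#' @return `roi_index` with `delta_sat` (and `kappa_true` when present)
#'   joined in.
#' @export
join_dyad_metadata <- function(roi_index, manifest) {
  keep <- intersect(c("dyad_id", "delta_sat", "kappa_true"), names(manifest))
  dplyr::left_join(roi_index, manifest[keep], by = "dyad_id")
}
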