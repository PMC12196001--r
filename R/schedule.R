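# Block-design paradigm: 7 x (60 s fixation + 114 s video) = 1218 s.

FIXATION_S <- 60
VIDEO_S <- 114
N_VIDEOS <- 7L

# The three counterbalanced stimulus orders used in the co-viewing paradigm.
VIDEO_SEQUENCES <- list(
  A = c("love", "disgust", "pride", "fear", "happiness", "sadness", "neutral"),
  B = c("sadness", "love", "neutral", "pride", "disgust", "fear", "happiness"),
  C = c("neutral", "sadness", "disgust", "happiness", "fear", "pride", "love")
)

VIDEO_CONDITIONS <- sort(VIDEO_SEQUENCES$A)

#' Emotional valence of each video condition
#'
#' Maps the seven video conditions to the three analysis conditions:
#' `positive` (happiness, love, pride), `negative` (sadness, fear, disgust)
#' and `baseline` (the neutral ocean video).
#'
#' @param condition Character vector of video condition labels.
#' @return Character vector of the same length with values
#'   `"positive"`, `"negative"` or `"baseline"`.
#' @export
#' @examples
#' condition_valence(c("love", "fear", "neutral"))
condition_valence <- function(condition) {
  valence <- c(happiness = "positive", love = "positive", pride = "positive",
               sadness = "negative", fear = "negative", disgust = "negative",
               neutral = "baseline")
  bad <- setdiff(unique(condition), names(valence))
  if (length(bad)) {
    abort(sprintf("Unknown video condition(s): %s.", paste(bad, collapse = ", ")),
          class = "dyadsync_parameter_error")
  }
  unname(valence[condition])
}

#' Build the block schedule for a stimulus sequence
#'
#' The paradigm alternates a 60 s fixation block with a 114 s video block,
#' seven times, for a total of 1218 s (20 min 18 s). Video block `k` starts at
#' `60 + 174 * (k - 1)` seconds. The order of the seven emotive videos depends
#' on which of the three counterbalanced sequences (A, B or C) the dyad was
#' assigned to.
#'
#' @param sequence_label One of `"A"`, `"B"`, `"C"`.
#' @return A tibble with one row per block and columns `block` (1..14),
#'   `condition` (`"fixation"` or a video condition), `onset` and `duration`
#'   in seconds, and `is_video`.
#' @export
#' @examples
#' sched <- make_schedule("A")
#' sum(sched$duration) # 1218
make_schedule <- function(sequence_label) {
  if (!is.character(sequence_label) || length(sequence_label) != 1L ||
      !sequence_label %in% names(VIDEO_SEQUENCES)) {
    abort("`sequence_label` must be one of \"A\", \"B\", \"C\".",
          class = "dyadsync_parameter_error")
  }
  videos <- VIDEO_SEQUENCES[[sequence_label]]
  k <- seq_len(N_VIDEOS)
  tibble::tibble(
    block = seq_len(2L * N_VIDEOS),
    condition = as.vector(rbind("fixation", videos)),
    onset = as.vector(rbind((k - 1) * (FIXATION_S + VIDEO_S),
                            FIXATION_S + (k - 1) * (FIXATION_S + VIDEO_S))),
    duration = rep(c(FIXATION_S, VIDEO_S), N_VIDEOS),
    is_video = rep(c(FALSE, TRUE), N_VIDEOS),
    sequence_label = sequence_label
  )
}

#' Video-onset markers implied by a schedule
#'
#' @param schedule A schedule tibble from [make_schedule()].
#' @return A tibble with columns `onset_s` and `condition`, one row per video.
#' @export
schedule_markers <- function(schedule) {
  assert_columns(schedule, c("onset", "condition", "is_video"), "`schedule`")
  schedule |>
    dplyr::filter(.data$is_video) |>
    dplyr::transmute(onset_s = .data$onset, condition = .data$condition)
}

#' Total duration of a schedule in seconds
#' @param schedule A schedule tibble from [make_schedule()].
#' @return A single number (seconds).
#' @export
schedule_duration <- function(schedule) sum(schedule$duration)
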