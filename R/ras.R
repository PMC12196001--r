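# Relationship Assessment Scale (RAS): 7 items on a 1..7 Likert scale.
# Items 4 ("How often do you wish you hadn't gotten into this relationship?")
# and 7 ("How many problems are there in your relationship?") are worded
# negatively and are reverse-scored with the instrument's standard key.

RAS_REVERSE_ITEMS <- c(4L, 7L)

#' Score a single Relationship Assessment Scale response
#'
#' Reverse-scores the negatively worded items as `8 - x`, then returns the
#' mean of the 7 transformed items, so the score lives on the same 1..7 scale
#' as the items.
#'
#' @param items Numeric vector of exactly 7 integer responses, each in 1..7.
#' @param reverse_items Integer positions of the reverse-keyed items
#'   (default items 4 and 7).
#' @return A single satisfaction score in `[1, 7]`.
#' @export
#' @examples
#' ras_score_items(c(4, 4, 4, 4, 4, 4, 4)) # 4
#' ras_score_items(c(7, 7, 7, 1, 7, 7, 1)) # 7
ras_score_items <- function(items, reverse_items = RAS_REVERSE_ITEMS) {
  if (length(items) != 7L) {
    abort("A RAS response must have exactly 7 items.",
          class = "dyadsync_validation_error")
  }
  if (anyNA(items) || !is.numeric(items) ||
      any(items < 1 | items > 7 | items != round(items))) {
    abort("RAS items must be integers in 1..7.",
          class = "dyadsync_validation_error")
  }
  x <- as.numeric(items)
  x[reverse_items] <- 8 - x[reverse_items]
  mean(x)
}

#' Score Relationship Assessment Scale responses in a data frame
#'
#' @param data A data frame with one row per participant and columns
#'   `item1` .. `item7` holding the raw Likert responses.
#' @param reverse_items Integer positions of the reverse-keyed items
#'   (default items 4 and 7).
#' @return The input as a tibble with an appended `ras_score` column.
#' @export
#' @examples
#' score_ras(data.frame(item1 = 4, item2 = 5, item3 = 4, item4 = 3,
#'                      item5 = 5, item6 = 6, item7 = 2))
score_ras <- function(data, reverse_items = RAS_REVERSE_ITEMS) {
  item_cols <- paste0("item", 1:7)
  assert_columns(data, item_cols, "`data`")
  items <- as.matrix(data[item_cols])
  data <- tibble::as_tibble(data)
  data$ras_score <- apply(items, 1L, ras_score_items,
                          reverse_items = reverse_items)
  data
}

#' Dyadic satisfaction difference
#'
#' The absolute difference between the two partners' satisfaction scores;
#' symmetric in its arguments and non-negative. Vectorised.
#'
#' @param score_a,score_b Satisfaction scores in `[1, 7]`.
#' @return `|score_a - score_b|`.
#' @export
#' @examples
#' satisfaction_difference(4.3, 4.4)
satisfaction_difference <- function(score_a, score_b) {
  if (any(!is.finite(score_a)) || any(!is.finite(score_b)) ||
      any(score_a < 1 | score_a > 7) || any(score_b < 1 | score_b > 7)) {
    abort("Satisfaction scores must be finite values in [1, 7].",
          class = "dyadsync_validation_error")
  }
  abs(score_a - score_b)
}
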