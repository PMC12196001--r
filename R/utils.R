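#' Derive a reproducible per-unit seed from a master seed
#'
#' Stable scheme used to give every simulated dyad (and every Monte-Carlo
#' replicate) its own RNG stream: `seed_i = (master * 48271 + i * 16807) mod
#' (2^31 - 1)`, evaluated in double precision (exact, since the product stays
#' far below 2^53). Resizing a cohort therefore never changes the recordings
#' of the dyads already in it.
#'
#' @param master Integer master seed.
#' @param index Positive integer index of the unit (dyad, replicate).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  as.integer((abs(master) * 48271 + index * 16807) %% 2147483647)
}

# shared validation helpers ---------------------------------------------------

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)),
          class = "dyadsync_parameter_error")
  }
  invisible(x)
}

assert_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "dyadsync_format_error")
  }
  invisible(data)
}

# next odd integer >= max(x, 3); moving-window lengths must be odd and >= 3
odd_window <- function(x) {
  k <- max(3L, as.integer(round(x)))
  if (k %% 2L == 0L) k <- k + 1L
  k
}
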