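# Cleaning chain for one dyad, in fixed order:
#   channel quality screen -> despike -> zero-phase band-pass -> Beer-Lambert.
# Despiking and filtering operate on the per-wavelength optical densities;
# the concentration conversion comes last.

#' Screen channels by gain and coefficient of variation
#'
#' A channel is retained iff `gain <= gain_max` and `cv <= cv_max` (strict
#' inequality excludes, so the boundary values pass); channels exceeding
#' either threshold are treated as background noise. Applied per subject.
#'
#' @param recording A `dyad_recording`.
#' @param gain_max,cv_max Exclusion thresholds (defaults 8 and 7.5).
#' @return A tibble (subject, channel, gain, cv, retained, reason) with
#'   `reason` a machine-readable label (`"gain"`, `"cv"`, `"gain+cv"`) for
#'   excluded channels and `NA` otherwise.
#' @export
filter_channels <- function(recording, gain_max = 8, cv_max = 7.5) {
  assert_scalar_number(gain_max, "gain_max", min = 1e-12)
  assert_scalar_number(cv_max, "cv_max", min = 1e-12)
  meta <- recording$channels
  assert_columns(meta, c("subject", "channel", "gain", "cv"),
                 "channel metadata")
  if (anyNA(meta$gain) || anyNA(meta$cv)) {
    bad <- meta[is.na(meta$gain) | is.na(meta$cv), ]
    abort(sprintf("Missing gain/CV metadata for subject %s channel %d.",
                  bad$subject[1], bad$channel[1]),
          class = "dyadsync_validation_error")
  }
  meta |>
    dplyr::mutate(
      retained = .data$gain <= gain_max & .data$cv <= cv_max,
      reason = dplyr::case_when(
        .data$gain > gain_max & .data$cv > cv_max ~ "gain+cv",
        .data$gain > gain_max ~ "gain",
        .data$cv > cv_max ~ "cv",
        TRUE ~ NA_character_
      )
    ) |>
    tibble::as_tibble()
}

#' Remove spike artefacts from a single-channel series
#'
#' Flags samples whose deviation from a centred moving median exceeds `k`
#' times a moving MAD-type robust scale, and replaces them by linear
#' interpolation between the nearest clean neighbours; flagged endpoints are
#' extended with the nearest clean value. The scale is the consistency-scaled
#' moving median of absolute successive differences, taken over a wider
#' window (at least 31 samples) than the detection median: successive
#' differences have no point mass at zero (the deviation-from-own-median
#' series does, wherever the signal is locally monotone), so the scale never
#' collapses, while a lone spike still cannot inflate it. Output length
#' equals input length; a spike-free series passes unchanged.
#'
#' @param series Numeric series.
#' @param fs Sampling rate (Hz).
#' @param window_s Median window length in seconds (>= 3 samples).
#' @param k Threshold multiplier on the moving MAD.
#' @return The cleaned numeric series, with an attribute `n_replaced`.
#' @export
despike <- function(series, fs, window_s = 1, k = 5) {
  n <- length(series)
  w <- odd_window(window_s * fs)
  if (window_s * fs < 3) {
    abort("`window_s` must cover at least 3 samples at this sampling rate.",
          class = "dyadsync_parameter_error")
  }
  if (n < w) return(structure(series, n_replaced = 0L))
  med <- runmed(series, w, endrule = "median")
  dev <- abs(series - med)
  w_mad <- odd_window(max(w, 31L))
  if (w_mad > n - 1L) w_mad <- odd_window(n - 2L)
  d <- abs(diff(series))
  scale_run <- 1.4826 / sqrt(2) * runmed(d, w_mad, endrule = "median")
  scale_run <- c(scale_run, scale_run[n - 1L])   # pad diff series to length n
  # guard against exactly-constant stretches where the scale collapses to zero
  floor_scale <- 1e-12 * max(1, max(abs(series)))
  flagged <- dev > k * pmax(scale_run, floor_scale)
  if (all(flagged)) {
    abort("All samples flagged as artefacts: channel is irrecoverable.",
          class = "dyadsync_irrecoverable_channel_error")
  }
  if (any(flagged)) {
    clean <- which(!flagged)
    series[flagged] <- approx(clean, series[clean], xout = which(flagged),
                              rule = 2)$y
  }
  structure(series, n_replaced = sum(flagged))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Demeans the series, then applies an order-`order` Butterworth band-pass
#' forward and backward (`signal::filtfilt`), so the net filter has zero
#' phase — inter-subject timing, which the synchrony index depends on, is
#' untouched. DC is removed exactly; length is preserved.
#'
#' @param series Numeric series.
#' @param fs Sampling rate (Hz).
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs / 2`.
#' @param order Butterworth order of each pass.
#' @return The filtered numeric series (mean approximately 0).
#' @export
bandpass <- function(series, fs, low_hz = 0.01, high_hz = 0.2, order = 3) {
  if (!is.finite(low_hz) || !is.finite(high_hz) ||
      low_hz <= 0 || low_hz >= high_hz || high_hz >= fs / 2) {
    abort("Band edges must satisfy 0 < low_hz < high_hz < fs/2.",
          class = "dyadsync_parameter_error")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, series - mean(series)))
}

#' Preprocess one dyad's recording to haemoglobin concentration series
#'
#' Runs the fixed cleaning chain per subject: quality screen
#' ([filter_channels()]), then per retained channel and wavelength
#' [despike()] and [bandpass()], then [beer_lambert_inverse()]. Channels
#' excluded for quality are absent from the output and appear exactly once
#' in the exclusion log with their reason.
#'
#' @param recording A `dyad_recording`.
#' @param gain_max,cv_max Quality-screen thresholds.
#' @param low_hz,high_hz,filter_order Band-pass parameters.
#' @param despike_window_s,despike_k Despiking parameters.
#' @param geometry A [channel_geometry()].
#' @return A `hemo_series` object: tibble `hemo` (subject, channel,
#'   sample_index, hbo, hbr), tibble `exclusions`, the retained channel sets,
#'   and the recording's metadata (sampling rate, markers, sequence,
#'   delta_sat) carried through.
#' @export
preprocess_dyad <- function(recording, gain_max = 8, cv_max = 7.5,
                            low_hz = 0.01, high_hz = 0.2, filter_order = 3,
                            despike_window_s = 1, despike_k = 5,
                            geometry = channel_geometry()) {
  quality <- filter_channels(recording, gain_max, cv_max)
  retained <- quality |> dplyr::filter(.data$retained)
  exclusions <- quality |>
    dplyr::filter(!.data$retained) |>
    dplyr::select("subject", "channel", "gain", "cv", "reason")
  fs <- recording$sampling_rate

  keep <- dplyr::semi_join(recording$od, retained, by = c("subject", "channel"))
  keep <- keep[order(keep$subject, keep$channel, keep$wavelength_nm,
                     keep$sample_index), ]
  key <- paste(keep$subject, keep$channel, keep$wavelength_nm)
  series <- split(keep$value, factor(key, unique(key)))
  bf <- signal::butter(filter_order, c(low_hz, high_hz) / (fs / 2),
                       type = "pass")
  a_inv <- solve(geometry_matrix(geometry))

  hbo_l <- vector("list", nrow(retained))
  hbr_l <- vector("list", nrow(retained))
  n <- NULL
  for (i in seq_len(nrow(retained))) {
    s <- retained$subject[i]; ch <- retained$channel[i]
    clean <- lapply(c(760, 850), function(wl) {
      x <- despike(series[[paste(s, ch, wl)]], fs, despike_window_s, despike_k)
      as.numeric(signal::filtfilt(bf, x - mean(x)))
    })
    conc <- a_inv %*% rbind(clean[[1]], clean[[2]])
    hbo_l[[i]] <- conc[1, ]
    hbr_l[[i]] <- conc[2, ]
    n <- length(clean[[1]])
  }
  hemo <- if (nrow(retained) == 0L) {
    tibble::tibble(subject = character(), channel = integer(),
                   sample_index = integer(), hbo = double(), hbr = double())
  } else {
    tibble::tibble(
      subject = rep(retained$subject, each = n),
      channel = rep(retained$channel, each = n),
      sample_index = rep(seq_len(n) - 1L, nrow(retained)),
      hbo = unlist(hbo_l, use.names = FALSE),
      hbr = unlist(hbr_l, use.names = FALSE)
    )
  }

  structure(list(
    dyad_id = recording$dyad_id,
    sequence_label = recording$sequence_label,
    sampling_rate = fs,
    hemo = hemo,
    retained = retained |> dplyr::select("subject", "channel"),
    exclusions = exclusions,
    markers = recording$markers,
    delta_sat = recording$delta_sat,
    kappa = recording$kappa %||% NA_real_
  ), class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("<hemo_series %s> %d retained subject-channels, %d excluded\n",
              x$dyad_id, nrow(x$retained), nrow(x$exclusions)))
  invisible(x)
}
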