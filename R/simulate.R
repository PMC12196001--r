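# Forward model for dyadic fNIRS co-viewing recordings.
#
# Per channel, each subject's true dHbO is
#   kappa * shared(t) + (1 - kappa) * individual(t) + noise(t)
# where shared() and individual() are HRF-convolved condition-locked responses
# (shared drawn once per dyad, individual per subject), kappa in [0, 1] is the
# inter-brain coupling strength, and the physiological noise (cardiac,
# respiratory, low-frequency waves, white noise, drift, motion spikes) is
# always drawn independently per subject. dHbR is -1/3 dHbO plus independent
# noise. The pair is mapped to 760/850 nm optical densities by the forward
# Beer-Lambert relation with the same geometry the preprocessing inverts.

ANALYSIS_CHANNELS <- c(4L, 6L, 7L, 11L, 13L, 14L, 16L, 19L)

#' Canonical double-gamma haemodynamic response function
#'
#' `dgamma(t, shape = peak_s) - dgamma(t, shape = undershoot_s) / ratio`,
#' sampled at `fs` over `span_s` seconds and normalised to unit sum so that a
#' convolved boxcar plateaus at its own amplitude.
#'
#' @param fs Sampling rate in Hz.
#' @param peak_s Time-to-peak of the positive lobe (s).
#' @param undershoot_s Time-to-peak of the undershoot (s).
#' @param ratio Peak-to-undershoot amplitude ratio divisor (canonical 6).
#' @param span_s Support of the kernel in seconds.
#' @return Numeric kernel of length `floor(span_s * fs) + 1`.
#' @export
hrf_double_gamma <- function(fs, peak_s = 6, undershoot_s = 16, ratio = 6,
                             span_s = 32) {
  t <- seq(0, span_s, by = 1 / fs)
  h <- dgamma(t, shape = peak_s, rate = 1) -
    dgamma(t, shape = undershoot_s, rate = 1) / ratio
  h / sum(h)
}

#' Simulation configuration for a dyadic fNIRS cohort
#'
#' Defaults reproduce the study conditions of the co-viewing paradigm: 15
#' dyads, 7.81 Hz sampling, the 60 s fixation / 114 s video block design, and
#' a coupling link `kappa = clip(beta0 + beta1 * delta_sat + N(0, sigma))`
#' through which the dyad's satisfaction difference modulates how much of the
#' condition-locked response the partners share. Amplitudes are in micromolar.
#'
#' @param n_dyads Number of dyads in the cohort.
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Integer channel IDs recorded (the 8 ventral-prefrontal
#'   analysis channels by default).
#' @param amplitudes Named condition response amplitudes (uM) for
#'   `positive`, `negative`, `baseline` videos.
#' @param coupling List `beta0`, `beta1`, `sigma` of the linear link from
#'   satisfaction difference to coupling strength kappa (clipped to `[0, 1]`).
#' @param hrf List of double-gamma parameters `peak_s`, `undershoot_s`,
#'   `ratio`.
#' @param noise Named amplitudes (uM) and frequencies (Hz) of the
#'   physiological noise components: `cardiac`/`cardiac_hz`,
#'   `respiratory`/`respiratory_hz`, `lowfreq`/`lowfreq_hz`, `white`
#'   (white-noise SD), `drift` (SD of the whole-recording linear drift
#'   excursion), `hbr_white` (independent dHbR noise SD).
#' @param block_gain_sd SD of the per-block multiplicative amplitude jitter
#'   (dyad-level for the shared component, subject-level for the individual
#'   component).
#' @param modulation_sd SD of the stimulus-locked within-block fluctuation,
#'   relative to the block amplitude: the video's moment-to-moment content
#'   modulating the neural drive. Drawn at dyad level for the shared
#'   component and per subject for the individual component; after HRF
#'   convolution its power lies inside the 0.01-0.2 Hz analysis band, so it
#'   is the component through which inter-brain coupling survives
#'   preprocessing.
#' @param spike_rate Expected motion spikes per second per channel.
#' @param spike_magnitude Spike amplitude (uM), random sign.
#' @param gain_range,cv_range Uniform ranges the per-channel `gain` and `cv`
#'   quality metadata are drawn from. The defaults generate channels that
#'   pass the `gain <= 8`, `cv <= 7.5` screen.
#' @param satisfaction List `mean`, `sd`, `item_sd`: latent satisfaction is
#'   `N(mean, sd)` truncated to `[1, 7]`, and the 7 Likert items are the
#'   latent score plus `N(0, item_sd)` noise, rounded and clamped (items 4
#'   and 7 reverse-keyed).
#' @param seed Master seed for [simulate_cohort()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_dyads = 15L,
                       sampling_rate = 7.81,
                       channels = ANALYSIS_CHANNELS,
                       amplitudes = c(positive = 0.35, negative = 0.35,
                                      baseline = 0.10),
                       coupling = list(beta0 = 0.3, beta1 = 0.35, sigma = 0.1),
                       hrf = list(peak_s = 6, undershoot_s = 16, ratio = 6),
                       noise = list(cardiac = 0.15, cardiac_hz = 1.1,
                                    respiratory = 0.10, respiratory_hz = 0.25,
                                    lowfreq = 0.10, lowfreq_hz = 0.1,
                                    white = 0.05, drift = 0.10,
                                    hbr_white = 0.02),
                       block_gain_sd = 0.3,
                       modulation_sd = 1,
                       spike_rate = 0.002,
                       spike_magnitude = 1.5,
                       gain_range = c(1, 7),
                       cv_range = c(0.5, 6),
                       satisfaction = list(mean = 4.4, sd = 0.5, item_sd = 0.5),
                       seed = 1L) {
  assert_scalar_number(n_dyads, "n_dyads", min = 1)
  assert_scalar_number(sampling_rate, "sampling_rate", min = 0.5)
  if (any(amplitudes < 0) ||
      !all(c("positive", "negative", "baseline") %in% names(amplitudes))) {
    abort("`amplitudes` must be non-negative and named positive/negative/baseline.",
          class = "dyadsync_parameter_error")
  }
  amp_noise <- unlist(noise[c("cardiac", "respiratory", "lowfreq", "white",
                              "drift", "hbr_white")])
  if (any(amp_noise < 0)) {
    abort("Noise amplitudes must be non-negative.",
          class = "dyadsync_parameter_error")
  }
  assert_scalar_number(coupling$sigma, "coupling$sigma", min = 0)
  structure(list(n_dyads = as.integer(n_dyads), sampling_rate = sampling_rate,
                 channels = as.integer(channels), amplitudes = amplitudes,
                 coupling = coupling, hrf = hrf, noise = noise,
                 block_gain_sd = block_gain_sd,
                 modulation_sd = modulation_sd, spike_rate = spike_rate,
                 spike_magnitude = spike_magnitude, gain_range = gain_range,
                 cv_range = cv_range, satisfaction = satisfaction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Condition-locked response for one channel: per video block, a boxcar drive
# with a multiplicative gain plus a stimulus-locked within-block fluctuation
# (the moment-to-moment content of the video modulating the response), all
# convolved with the HRF. The within-block fluctuation matters: after HRF
# smoothing its power sits in ~0.01-0.1 Hz, inside the analysis band, whereas
# the 114 s block envelope itself (fundamental ~0.006 Hz) is mostly removed
# by the 0.01 Hz high-pass edge.
condition_response <- function(schedule, fs, n, amplitudes, block_gains, kernel,
                               modulation_sd = 1) {
  videos <- schedule[schedule$is_video, ]
  box <- numeric(n)
  for (b in seq_len(nrow(videos))) {
    start <- floor(videos$onset[b] * fs)           # 0-based sample
    len <- floor(videos$duration[b] * fs)
    amp <- amplitudes[[condition_valence(videos$condition[b])]]
    idx <- (start + 1L):min(n, start + len)
    drive <- 1 + modulation_sd * rnorm(length(idx))
    box[idx] <- box[idx] + amp * block_gains[b] * drive
  }
  stats::convolve(box, rev(kernel), type = "open")[seq_len(n)]
}

sinusoid <- function(t, amplitude, freq_hz) {
  amplitude * sin(2 * pi * freq_hz * t + runif(1, 0, 2 * pi))
}

subject_noise <- function(t, n, fs, noise, spike_rate, spike_magnitude) {
  nz <- sinusoid(t, noise$cardiac, noise$cardiac_hz) +
    sinusoid(t, noise$respiratory, noise$respiratory_hz) +
    sinusoid(t, noise$lowfreq, noise$lowfreq_hz) +
    rnorm(n, 0, noise$white) +
    rnorm(1, 0, noise$drift) * (t - mean(t)) / max(t[n], 1)
  n_spikes <- stats::rpois(1, spike_rate * n / fs)
  if (n_spikes > 0) {
    at <- sample.int(n, n_spikes)
    nz[at] <- nz[at] + sample(c(-1, 1), n_spikes, replace = TRUE) * spike_magnitude
  }
  nz
}

draw_ras_items <- function(latent, item_sd) {
  raw <- pmin(7, pmax(1, round(latent + rnorm(7, 0, item_sd))))
  raw[RAS_REVERSE_ITEMS] <- 8 - raw[RAS_REVERSE_ITEMS]
  as.integer(raw)
}

#' Simulate one dyad's two-wavelength fNIRS recording
#'
#' Builds the coupled condition-locked haemodynamics for both partners,
#' degrades them with subject-independent physiological noise, drift and
#' motion spikes, and maps them to 760/850 nm optical densities with the
#' forward Beer-Lambert relation. Fully deterministic given
#' `(config, delta_sat, dyad_seed)`.
#'
#' @param config A [sim_config()].
#' @param delta_sat The dyad's satisfaction difference (>= 0), which sets the
#'   coupling strength through the configured link.
#' @param dyad_seed Integer seed for this dyad's random draws.
#' @param sequence_label Stimulus sequence `"A"`, `"B"` or `"C"`.
#' @param dyad_id Identifier stored in the recording.
#' @param kappa Optional fixed coupling strength in `[0, 1]`, overriding the
#'   link (used for calibration experiments).
#' @param ras Optional list of two integer item vectors (subjects a, b)
#'   recorded as the questionnaire responses.
#' @param geometry A [channel_geometry()] for the forward optical map.
#' @return A `dyad_recording` object: tibbles `od` (subject, channel,
#'   wavelength_nm, sample_index, value), `channels` (gain/cv metadata) and
#'   `markers`, plus sampling rate, satisfaction metadata and the true
#'   `kappa`.
#' @export
simulate_dyad <- function(config, delta_sat, dyad_seed,
                          sequence_label = "A", dyad_id = "dyad01",
                          kappa = NULL, ras = NULL,
                          geometry = channel_geometry()) {
  assert_scalar_number(delta_sat, "delta_sat", min = 0, max = 6)
  set.seed(as.integer(dyad_seed))
  fs <- config$sampling_rate
  schedule <- make_schedule(sequence_label)
  n <- floor(schedule_duration(schedule) * fs)
  t <- (seq_len(n) - 1L) / fs
  kernel <- hrf_double_gamma(fs, config$hrf$peak_s, config$hrf$undershoot_s,
                             config$hrf$ratio)
  if (is.null(kappa)) {
    kappa <- config$coupling$beta0 + config$coupling$beta1 * delta_sat +
      rnorm(1, 0, config$coupling$sigma)
  }
  kappa <- min(1, max(0, kappa))

  n_video <- sum(schedule$is_video)
  nch <- length(config$channels)
  vals <- vector("list", 2L * nch)
  subj_v <- character(2L * nch)
  chan_v <- integer(2L * nch)
  gains <- cvs <- numeric(2L * nch)
  i <- 0L
  for (ch in config$channels) {
    shared <- condition_response(schedule, fs, n, config$amplitudes,
                                 rnorm(n_video, 1, config$block_gain_sd),
                                 kernel, config$modulation_sd)
    for (subject in c("a", "b")) {
      indiv <- condition_response(schedule, fs, n, config$amplitudes,
                                  rnorm(n_video, 1, config$block_gain_sd),
                                  kernel, config$modulation_sd)
      hbo <- kappa * shared + (1 - kappa) * indiv +
        subject_noise(t, n, fs, config$noise, config$spike_rate,
                      config$spike_magnitude)
      hbr <- -hbo / 3 + rnorm(n, 0, config$noise$hbr_white)
      ods <- beer_lambert_forward(hbo, hbr, geometry)
      i <- i + 1L
      vals[[i]] <- c(ods$od_760, ods$od_850)
      subj_v[i] <- subject
      chan_v[i] <- ch
      gains[i] <- runif(1, config$gain_range[1], config$gain_range[2])
      cvs[i] <- runif(1, config$cv_range[1], config$cv_range[2])
    }
  }
  od <- tibble::tibble(
    subject = rep(subj_v, each = 2L * n),
    channel = rep(chan_v, each = 2L * n),
    wavelength_nm = rep(rep(c(760L, 850L), each = n), 2L * nch),
    sample_index = rep(rep(seq_len(n) - 1L, 2L), 2L * nch),
    value = unlist(vals, use.names = FALSE)
  )
  chmeta <- tibble::tibble(subject = subj_v, channel = chan_v,
                           gain = gains, cv = cvs)

  structure(list(
    dyad_id = dyad_id,
    sequence_label = sequence_label,
    sampling_rate = fs,
    n_samples = n,
    od = dplyr::bind_rows(od),
    channels = dplyr::bind_rows(chmeta),
    markers = schedule_markers(schedule),
    ras = ras,
    delta_sat = delta_sat,
    kappa = kappa
  ), class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf(
    "<dyad_recording %s> sequence %s, %d channels x 2 subjects x 2 wavelengths, %d samples @ %.2f Hz\n",
    x$dyad_id, x$sequence_label, length(unique(x$od$channel)), x$n_samples,
    x$sampling_rate))
  invisible(x)
}

#' Simulate a cohort of dyads
#'
#' Draws each partner's latent satisfaction from the configured truncated
#' normal, generates 7-item questionnaire responses, scores them with
#' [score_ras()], assigns the three stimulus sequences round-robin through a
#' seeded permutation, and simulates each dyad with its own derived seed
#' ([derive_seed()]), so the cohort is reproducible and stable under
#' resizing.
#'
#' @param config A [sim_config()]; `config$seed` is the master seed.
#' @param geometry A [channel_geometry()].
#' @return A list of `dyad_recording` objects with a `manifest` attribute:
#'   a tibble (dyad_id, sequence_label, score_a, score_b, delta_sat,
#'   kappa_true).
#' @export
simulate_cohort <- function(config, geometry = channel_geometry()) {
  if (config$n_dyads < 1L) {
    abort("`n_dyads` must be at least 1.", class = "dyadsync_parameter_error")
  }
  set.seed(config$seed)
  n <- config$n_dyads
  sat <- config$satisfaction
  draw_latent <- function(k) {
    x <- rnorm(k, sat$mean, sat$sd)
    while (any(bad <- x < 1 | x > 7)) x[bad] <- rnorm(sum(bad), sat$mean, sat$sd)
    x
  }
  latent_a <- draw_latent(n)
  latent_b <- draw_latent(n)
  items_a <- lapply(latent_a, draw_ras_items, item_sd = sat$item_sd)
  items_b <- lapply(latent_b, draw_ras_items, item_sd = sat$item_sd)
  score_a <- vapply(items_a, ras_score_items, numeric(1))
  score_b <- vapply(items_b, ras_score_items, numeric(1))
  sequences <- sample(rep_len(c("A", "B", "C"), n))
  dyad_ids <- sprintf("dyad%02d", seq_len(n))

  recordings <- lapply(seq_len(n), function(i) {
    simulate_dyad(config,
                  delta_sat = satisfaction_difference(score_a[i], score_b[i]),
                  dyad_seed = derive_seed(config$seed, i),
                  sequence_label = sequences[i], dyad_id = dyad_ids[i],
                  ras = list(a = items_a[[i]], b = items_b[[i]]),
                  geometry = geometry)
  })
  names(recordings) <- dyad_ids
  attr(recordings, "manifest") <- tibble::tibble(
    dyad_id = dyad_ids, sequence_label = sequences,
    score_a = score_a, score_b = score_b,
    delta_sat = satisfaction_difference(score_a, score_b),
    kappa_true = unname(vapply(recordings, function(r) r$kappa, numeric(1)))
  )
  recordings
}

#' Cohort manifest
#'
#' @param cohort A list of recordings from [simulate_cohort()].
#' @return The manifest tibble (dyad_id, sequence_label, scores, delta_sat,
#'   kappa_true).
#' @export
cohort_manifest <- function(cohort) {
  m <- attr(cohort, "manifest")
  if (is.null(m)) {
    m <- tibble::tibble(
      dyad_id = vapply(cohort, function(r) r$dyad_id, character(1)),
      sequence_label = vapply(cohort, function(r) r$sequence_label, character(1)),
      score_a = NA_real_, score_b = NA_real_,
      delta_sat = vapply(cohort, function(r) r$delta_sat %||% NA_real_, numeric(1)),
      kappa_true = vapply(cohort, function(r) r$kappa %||% NA_real_, numeric(1))
    )
  }
  m
}
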