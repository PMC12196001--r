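test_that("recordings are deterministic in (config, delta_sat, dyad_seed)", {
  cfg <- sim_config(n_dyads = 1, seed = 5)
  r1 <- simulate_dyad(cfg, 0.7, 123, "B")
  r2 <- simulate_dyad(cfg, 0.7, 123, "B")
  expect_equal(r1$od, r2$od)
  expect_equal(r1$channels, r2$channels)
  expect_equal(r1$kappa, r2$kappa)
})

test_that("fully coupled noise-free partners are identical per channel", {
  cfg <- quiet_sim_config()
  rec <- simulate_dyad(cfg, 0, 99, "A", kappa = 1)
  wide <- tidyr::pivot_wider(rec$od, names_from = "subject",
                             values_from = "value")
  expect_equal(wide$a, wide$b, tolerance = 1e-12)
})

test_that("series length is floor(1218 x sampling rate) and both subjects share it", {
  for (fs in c(7.81, 1)) {
    rec <- simulate_dyad(sim_config(sampling_rate = fs), 0.5, 3, "A")
    expect_equal(rec$n_samples, floor(1218 * fs))
    lens <- dplyr::count(rec$od, subject, channel, wavelength_nm)
    expect_true(all(lens$n == rec$n_samples))
  }
})

test_that("noise-free recordings invert to the simulated anticorrelated chromophores", {
  cfg <- quiet_sim_config()
  rec <- simulate_dyad(cfg, 0.2, 17, "A", kappa = 0.5)
  one <- dplyr::filter(rec$od, subject == "a", channel == 7)
  od760 <- one$value[one$wavelength_nm == 760]
  od850 <- one$value[one$wavelength_nm == 850]
  conc <- beer_lambert_inverse(od760, od850)
  # with hbr_white = 0 the simulator sets dHbR = -dHbO / 3 exactly
  expect_equal(conc$hbr, -conc$hbo / 3, tolerance = 1e-9)
})

test_that("cardiac noise peaks near 1.1 Hz in the raw series and is gone after band-pass", {
  cfg <- sim_config(noise = list(cardiac = 2, cardiac_hz = 1.1,
                                 respiratory = 0, respiratory_hz = 0.25,
                                 lowfreq = 0, lowfreq_hz = 0.1,
                                 white = 0.01, drift = 0, hbr_white = 0),
                    spike_rate = 0)
  rec <- simulate_dyad(cfg, 0.5, 31, "A")
  x <- dplyr::filter(rec$od, subject == "a", channel == 4,
                     wavelength_nm == 850)$value
  fs <- cfg$sampling_rate
  spec <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                            taper = 0, detrend = TRUE)
  expect_lt(abs(spec$freq[which.max(spec$spec)] - 1.1), 0.1)

  filtered <- bandpass(x, fs)
  spec_f <- stats::spec.pgram(stats::ts(filtered, frequency = fs),
                              plot = FALSE, taper = 0, detrend = TRUE)
  expect_lt(spec_f$freq[which.max(spec_f$spec)], 0.3)
})

test_that("the coupling link transfers the satisfaction difference with the configured sign", {
  cfg <- sim_config(n_dyads = 100, sampling_rate = 1,
                    coupling = list(beta0 = 0.8, beta1 = -0.35, sigma = 0.02),
                    seed = 61)
  cohort <- simulate_cohort(cfg)
  m <- cohort_manifest(cohort)
  expect_lt(cor(m$delta_sat, m$kappa_true), 0)
})

test_that("cohorts are reproducible, round-robin sequenced, and sized as configured", {
  cfg <- sim_config(n_dyads = 15, sampling_rate = 1, seed = 42)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_equal(length(c1), 15L)
  m1 <- cohort_manifest(c1); m2 <- cohort_manifest(c2)
  expect_equal(m1$delta_sat, m2$delta_sat)
  expect_equal(sort(as.integer(table(m1$sequence_label))), c(5L, 5L, 5L))
  expect_true(all(m1$kappa_true >= 0 & m1$kappa_true <= 1))
  expect_true(all(m1$score_a >= 1 & m1$score_a <= 7))
  expect_equal(m1$delta_sat, satisfaction_difference(m1$score_a, m1$score_b))
  expect_error(simulate_cohort(sim_config(n_dyads = 0)),
               class = "dyadsync_parameter_error")
})

test_that("stronger coupling lowers the downstream normalized distance", {
  # 50 replicate dyads per coupling level at reduced rate, full preprocessing
  cfg <- sim_config(sampling_rate = 1, seed = 1)
  mean_index <- vapply(c(0.1, 0.9), function(k) {
    mean(vapply(1:50, function(r) {
      rec <- simulate_dyad(cfg, 0.5, derive_seed(1000 * k, r), "A", kappa = k)
      h <- preprocess_dyad(rec, despike_window_s = 3)
      mean(compute_dyad_synchrony(h)$normalized_distance)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean_index[2], mean_index[1])
})

test_that("per-dyad seeds are stable, distinct and below 2^31", {
  s <- vapply(1:50, function(i) derive_seed(123456, i), integer(1))
  expect_equal(length(unique(s)), 50L)
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(derive_seed(123456, 7), derive_seed(123456, 7))
})
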