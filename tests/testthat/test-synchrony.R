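test_that("video segments at 7.81 Hz are 890 samples, first video starting at sample 468", {
  cfg <- quiet_sim_config()
  h <- preprocess_dyad(simulate_dyad(cfg, 0.5, 8, "A"))
  segs <- segment_blocks(h)
  counts <- dplyr::count(segs, subject, channel, block)
  expect_true(all(counts$n == 890L))             # floor(114 * 7.81)
  expect_equal(length(unique(segs$block)), 7L)
  expect_equal(min(segs$sample_index[segs$block == 1]), 468L)  # floor(60 * 7.81)
  # fixation samples are not segmented
  expect_lt(nrow(segs), nrow(h$hemo))
})

test_that("segments carry the sequence's stimulus order", {
  cfg <- quiet_sim_config()
  for (label in c("A", "C")) {
    h <- preprocess_dyad(simulate_dyad(cfg, 0.5, 8, label))
    segs <- segment_blocks(h)
    order_seen <- segs |>
      dplyr::distinct(block, condition) |>
      dplyr::arrange(block) |>
      dplyr::pull(condition)
    sched <- make_schedule(label)
    expect_equal(order_seen, sched$condition[sched$is_video])
  }
})

test_that("a schedule that overruns the series names the offending block", {
  h <- make_hemo(list(a = list(`4` = rnorm(100)), b = list(`4` = rnorm(100))),
                 fs = 7.81, sequence_label = "A")
  expect_error(segment_blocks(h), regexp = "love",
               class = "dyadsync_truncation_error")
  expect_error(compute_dyad_synchrony(h), class = "dyadsync_truncation_error")
})

test_that("identical partners give an all-zero synchrony table of channels x 7 rows", {
  v <- rnorm(9512)
  h <- make_hemo(list(a = list(`4` = v, `7` = v * 2),
                      b = list(`4` = v, `7` = v * 2)))
  tab <- compute_dyad_synchrony(h)
  expect_equal(nrow(tab), 2L * 7L)
  expect_true(all(tab$normalized_distance == 0))
})

test_that("dyad synchrony rows equal independent per-segment alignments", {
  cfg <- quiet_sim_config(sampling_rate = 1)
  h <- preprocess_dyad(simulate_dyad(cfg, 0.5, 14, "B", kappa = 0.4),
                       despike_window_s = 3)
  tab <- compute_dyad_synchrony(h)
  segs <- segment_blocks(h)
  for (row in sample(nrow(tab), 10)) {
    ch <- tab$channel[row]; b <- tab$block[row]
    xa <- segs$value[segs$subject == "a" & segs$channel == ch & segs$block == b]
    xb <- segs$value[segs$subject == "b" & segs$channel == ch & segs$block == b]
    expect_equal(tab$normalized_distance[row],
                 dtw_align(xa, xb)$normalized_distance)
  }
})

test_that("channels lost in one subject are absent, and losing one never moves the other ROI", {
  v <- lapply(1:8, function(i) rnorm(9512, sd = 0.1))
  names(v) <- as.character(c(4, 6, 7, 11, 13, 14, 16, 19))
  w <- lapply(v, function(x) x + rnorm(9512, sd = 0.05))
  full <- compute_dyad_synchrony(make_hemo(list(a = v, b = w)))
  dropped <- compute_dyad_synchrony(make_hemo(list(a = v[-1], b = w)))
  expect_false(4L %in% dropped$channel)
  agg_full <- aggregate_roi_condition(full)
  agg_drop <- aggregate_roi_condition(dropped)
  right_full <- dplyr::filter(agg_full, roi == "frontal_right")
  right_drop <- dplyr::filter(agg_drop, roi == "frontal_right")
  expect_equal(right_full$index, right_drop$index)
  left_drop <- dplyr::filter(agg_drop, roi == "frontal_left")
  expect_true(all(left_drop$n_channels_used == 3L))
})

test_that("ROI aggregation is the mean of channel means, right ROI using channels 13/14/16/19", {
  map <- channel_roi_map()
  expect_equal(sort(map$channel[map$roi == "frontal_left"]), c(4L, 6L, 7L, 11L))
  expect_equal(sort(map$channel[map$roi == "frontal_right"]), c(13L, 14L, 16L, 19L))

  # constant distances aggregate to the constant
  const <- tidyr::expand_grid(dyad_id = "d", channel = map$channel,
                              block = 1:7) |>
    dplyr::mutate(condition = make_schedule("A")$condition[make_schedule("A")$is_video][block],
                  normalized_distance = 0.42)
  agg <- aggregate_roi_condition(const)
  expect_equal(nrow(agg), 6L)  # 2 ROIs x 3 conditions
  expect_true(all(agg$index == 0.42))

  # hand-computed toy: 3 rows in the right ROI, one condition
  toy <- tibble::tibble(dyad_id = "d", channel = c(13L, 14L, 16L),
                        block = c(2L, 2L, 4L),
                        condition = c("disgust", "disgust", "fear"),
                        normalized_distance = c(0.2, 0.4, 0.9))
  agg_toy <- aggregate_roi_condition(toy)
  # channels -> ROI within block: block 2 mean 0.3, block 4 mean 0.9;
  # blocks -> condition (both negative): (0.3 + 0.9) / 2
  expect_equal(agg_toy$index, 0.6)
  expect_equal(agg_toy$condition, "negative")
})

test_that("aggregation is invariant to row permutations", {
  set.seed(55)
  tab <- tidyr::expand_grid(dyad_id = c("d1", "d2"),
                            channel = channel_roi_map()$channel,
                            block = 1:7) |>
    dplyr::mutate(condition = make_schedule("B")$condition[make_schedule("B")$is_video][block],
                  normalized_distance = runif(dplyr::n()))
  a1 <- aggregate_roi_condition(tab) |> dplyr::arrange(dyad_id, roi, condition)
  a2 <- aggregate_roi_condition(tab[sample(nrow(tab)), ]) |>
    dplyr::arrange(dyad_id, roi, condition)
  expect_equal(a1, a2)
  # exactly 2 ROIs x 3 conditions per dyad
  expect_equal(nrow(a1), 12L)
})

test_that("dyad metadata joins by dyad_id", {
  agg <- tibble::tibble(dyad_id = c("d1", "d2"), roi = "frontal_right",
                        condition = "positive", index = c(0.1, 0.2),
                        n_channels_used = 4L)
  manifest <- tibble::tibble(dyad_id = c("d1", "d2"), delta_sat = c(0.3, 1.1),
                             kappa_true = c(0.5, 0.8))
  out <- join_dyad_metadata(agg, manifest)
  expect_equal(out$delta_sat, c(0.3, 1.1))
  expect_equal(out$kappa_true, c(0.5, 0.8))
})
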