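test_that("Kruskal-Wallis reproduces hand-ranked toys", {
  # groups {1,2} vs {3,4}: R1 = 3, R2 = 7, N = 4 -> H = 2.4
  d <- data.frame(y = c(1, 2, 3, 4), g = rep(c("a", "b"), each = 2))
  out <- kruskal_wallis(d, "y", "g")
  expect_equal(out$statistic, 2.4, tolerance = 1e-12)
  expect_equal(out$df, 1)

  # identical groups -> H = 0
  same <- data.frame(y = c(1, 2, 1, 2), g = rep(c("a", "b"), each = 2))
  expect_equal(kruskal_wallis(same, "y", "g")$statistic, 0, tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches the closed-form tie-corrected oracle on random data", {
  set.seed(19)
  for (i in 1:20) {
    groups <- list(sample(1:6, 8, replace = TRUE),
                   sample(1:6, 6, replace = TRUE),
                   sample(1:6, 7, replace = TRUE))
    d <- data.frame(y = unlist(groups),
                    g = rep(c("a", "b", "c"), times = lengths(groups)))
    expect_equal(kruskal_wallis(d, "y", "g")$statistic, kw_oracle(groups),
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(23)
  d <- data.frame(y = rexp(30), g = rep(c("a", "b", "c"), 10))
  h0 <- kruskal_wallis(d, "y", "g")$statistic
  for (f in list(exp, function(x) x^3, function(x) log(x + 1))) {
    d2 <- d; d2$y <- f(d$y)
    expect_equal(kruskal_wallis(d2, "y", "g")$statistic, h0, tolerance = 1e-10)
  }
})

test_that("the two-group Kruskal-Wallis is the same operation with df = 1", {
  set.seed(29)
  d <- data.frame(y = rnorm(30), g = rep(c("emotion", "baseline"), 15))
  out <- kruskal_wallis(d, "y", "g")
  expect_equal(out$df, 1)
  expect_equal(out$statistic,
               kw_oracle(split(d$y, d$g)), tolerance = 1e-10)
})

test_that("degenerate all-identical data returns H = 0 with a warning", {
  d <- data.frame(y = rep(1, 10), g = rep(c("a", "b"), 5))
  expect_warning(out <- kruskal_wallis(d, "y", "g"),
                 class = "dyadsync_degenerate_ties")
  expect_equal(out$statistic, 0)
})

test_that("OLS interpolates noise-free data exactly and reports residual df = rows - 3", {
  set.seed(31)
  input <- tibble::tibble(
    dyad_id = rep(sprintf("d%02d", 1:15), each = 2),
    roi = "frontal_right",
    condition = rep(c("positive", "negative"), 15),
    satisfaction_difference = rep(runif(15, 0, 2), each = 2),
    emotion_positive = rep(c(1L, 0L), 15)
  )
  input$index <- 2 + 3 * input$satisfaction_difference - 1 * input$emotion_positive
  fit <- fit_distance_regression(input)
  # summary.lm warns about the (deliberately) perfect fit
  est <- suppressWarnings(tidy(fit)$estimate)
  expect_equal(est, c(2, 3, -1), tolerance = 1e-10)
  gl <- suppressWarnings(glance(fit))
  expect_equal(gl$df.residual, 27)   # 30 rows - 3 coefficients
  expect_equal(gl$nobs, 30)
})

test_that("OLS coefficients match the normal-equations oracle to 1e-10", {
  set.seed(37)
  input <- tibble::tibble(
    satisfaction_difference = runif(24, 0, 2),
    emotion_positive = rep(c(1L, 0L), 12),
    index = rnorm(24)
  )
  fit <- fit_distance_regression(input)
  X <- cbind(1, input$satisfaction_difference, input$emotion_positive)
  expect_equal(tidy(fit)$estimate, ols_oracle(X, input$index),
               tolerance = 1e-10)
  # residuals orthogonal to every design column
  resid <- input$index - X %*% tidy(fit)$estimate
  expect_true(all(abs(t(X) %*% resid) < 1e-8 * max(abs(input$index))))
})

test_that("regression rejects rank-deficient designs and tiny inputs", {
  bad <- tibble::tibble(satisfaction_difference = rep(0.5, 10),
                        emotion_positive = rep(1L, 10), index = rnorm(10))
  expect_error(fit_distance_regression(bad),
               class = "dyadsync_collinearity_error")
  expect_error(fit_distance_regression(bad[1:3, ]),
               class = "dyadsync_parameter_error")
})

test_that("regression input keeps positive/negative rows only, dummy-coded positive = 1", {
  roi_index <- tidyr::expand_grid(dyad_id = c("d1", "d2"),
                                  roi = c("frontal_left", "frontal_right"),
                                  condition = c("positive", "negative", "baseline")) |>
    dplyr::mutate(index = seq(0.1, by = 0.1, length.out = dplyr::n()),
                  delta_sat = 0.5)
  input <- regression_input(roi_index, roi = "frontal_right")
  expect_equal(nrow(input), 4L)
  expect_false("baseline" %in% input$condition)
  expect_equal(input$emotion_positive, as.integer(input$condition == "positive"))
})

test_that("Pearson correlation matches the covariance-formula oracle and its own t-based p", {
  x <- c(1, 2, 4, 5, 9)
  y <- c(2, 1, 5, 4, 8)
  out <- pearson_corr(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$estimate, r_oracle, tolerance = 1e-12)
  t_stat <- out$estimate * sqrt(out$n - 2) / sqrt(1 - out$estimate^2)
  expect_equal(out$p.value, 2 * pt(-abs(t_stat), out$n - 2), tolerance = 1e-12)
  expect_equal(pearson_corr(x, x)$estimate, 1)
})

test_that("the r-to-p conversion at r = -0.47, n = 15 is consistent with the two-tailed t formula", {
  t_stat <- -0.47 * sqrt(13) / sqrt(1 - 0.47^2)
  p <- 2 * pt(t_stat, 13)
  # printed as 0.079 in the study (computed from unrounded r); the rounded r
  # reproduces it to half a percentage point
  expect_lt(abs(p - 0.079), 0.005)
})

test_that("Pearson rejects constant and short inputs", {
  expect_error(pearson_corr(rep(1, 5), rnorm(5)),
               class = "dyadsync_undefined_correlation_error")
  expect_error(pearson_corr(1:2, 1:2), class = "dyadsync_parameter_error")
})

test_that("the statistical battery populates every component on a toy cohort", {
  set.seed(43)
  roi_index <- tidyr::expand_grid(dyad_id = sprintf("d%02d", 1:15),
                                  roi = c("frontal_left", "frontal_right"),
                                  condition = c("positive", "negative", "baseline")) |>
    dplyr::mutate(index = runif(dplyr::n(), 0.1, 0.5)) |>
    dplyr::left_join(tibble::tibble(dyad_id = sprintf("d%02d", 1:15),
                                    delta_sat = runif(15, 0, 2)),
                     by = "dyad_id")
  st <- synchrony_stats(roi_index)
  expect_s3_class(st, "synchrony_stats")
  expect_equal(st$kw_three_way$df, 2)
  expect_equal(st$kw_three_way$n, 45)
  expect_equal(st$kw_two_way$df, 1)
  expect_gte(st$kw_three_way$statistic, 0)
  expect_named(st$regression, c("frontal_left", "frontal_right"))
  expect_equal(st$regression$frontal_right$fit$df.residual, 27)
  expect_equal(st$pearson$n, 15)
  expect_lte(abs(st$pearson$estimate), 1)

  td <- tidy(st)
  expect_true(all(c("kruskal_wallis_3way", "kruskal_wallis_2way",
                    "regression_frontal_right", "pearson") %in% td$analysis))
  gl <- glance(st)
  expect_equal(gl$df_residual, 27)
  expect_true(all(c(gl$kw3_p, gl$slope_p, gl$pearson_p) >= 0 &
                  c(gl$kw3_p, gl$slope_p, gl$pearson_p) <= 1))
})
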