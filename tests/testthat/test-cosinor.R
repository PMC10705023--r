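test_that("a noiseless cosine is recovered exactly", {
  y <- 10 + 3 * cos(2 * pi * (0:23 - 5) / 24)
  fit <- cosinor_fit(y)
  expect_equal(fit$mesor, 10, tolerance = 1e-9)
  expect_equal(fit$amplitude, 3, tolerance = 1e-9)
  expect_equal(fit$acrophase, 5, tolerance = 1e-9)
  expect_equal(fit$oscillation_range, 6, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
  expect_equal(fit$rhythmicity_index, 6, tolerance = 1e-8)
  expect_lt(fit$p_value, 1e-10)
  expect_equal(predict(fit), fitted(fit))
})

test_that("a constant day is degenerate: zero amplitude, p = 1, undefined acrophase", {
  fit <- cosinor_fit(rep(7, 24))
  expect_identical(fit$amplitude, 0)
  expect_identical(fit$p_value, 1)
  expect_true(is.na(fit$acrophase))
  expect_identical(fit$rhythmicity_index, 0)
})

test_that("fit invariants hold on noisy days: RI and range identities", {
  set.seed(41)
  for (i in 1:25) {
    y <- 20 + 5 * cos(2 * pi * (0:23 - stats::runif(1, 0, 24)) / 24) +
      stats::rnorm(24, 0, 2)
    fit <- cosinor_fit(y)
    expect_identical(fit$oscillation_range, 2 * fit$amplitude)
    expect_identical(fit$rhythmicity_index,
                     fit$pearson_r * fit$oscillation_range)
    expect_true(fit$acrophase >= 0 && fit$acrophase < 24)
    expect_true(fit$p_value >= 0 && fit$p_value <= 1)
    # residuals + fitted reconstruct the data
    expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-12)
  }
})

test_that("acrophase agrees with the profiled grid-search oracle on noisy days", {
  set.seed(42)
  for (i in 1:8) {
    phi <- stats::runif(1, 0, 24)
    y <- 15 + 4 * cos(2 * pi * (0:23 - phi) / 24) + stats::rnorm(24, 0, 1)
    fit <- cosinor_fit(y)
    oracle <- grid_cosinor_acrophase(y, step = 0.01)
    d <- abs(fit$acrophase - oracle) %% 24
    expect_lt(min(d, 24 - d), 0.011)
  }
})

test_that("circular shift equivariance: rolling the day rolls the acrophase", {
  set.seed(43)
  y <- 15 + 4 * cos(2 * pi * (0:23 - 6.3) / 24) + stats::rnorm(24, 0, 1)
  base <- cosinor_fit(y)
  for (k in c(1, 5, 11, 23)) {
    shifted <- cosinor_fit(y[((0:23 - k) %% 24) + 1])
    d <- (shifted$acrophase - base$acrophase) %% 24
    expect_equal(d, k, tolerance = 1e-9)
    expect_equal(shifted$amplitude, base$amplitude, tolerance = 1e-9)
    expect_equal(shifted$p_value, base$p_value, tolerance = 1e-9)
  }
})

test_that("scale equivariance: amplitude-like quantities scale, phase and p do not", {
  set.seed(44)
  y <- 15 + 4 * cos(2 * pi * (0:23 - 2.2) / 24) + stats::rnorm(24, 0, 1)
  base <- cosinor_fit(y)
  scaled <- cosinor_fit(y * 3.7)
  expect_equal(scaled$amplitude, 3.7 * base$amplitude, tolerance = 1e-9)
  expect_equal(scaled$oscillation_range, 3.7 * base$oscillation_range,
               tolerance = 1e-9)
  expect_equal(scaled$rhythmicity_index, 3.7 * base$rhythmicity_index,
               tolerance = 1e-9)
  expect_equal(scaled$acrophase, base$acrophase, tolerance = 1e-9)
  expect_equal(scaled$pearson_r, base$pearson_r, tolerance = 1e-9)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-9)
})

test_that("parameter recovery over 200 noisy days; F-test rejects rhythmic days", {
  set.seed(45)
  errs <- numeric(200)
  ps <- numeric(200)
  for (i in 1:200) {
    phi <- stats::runif(1, 0, 24)
    y <- 20 + 5 * cos(2 * pi * (0:23 - phi) / 24) + stats::rnorm(24, 0, 0.5)
    fit <- cosinor_fit(y)
    d <- abs(fit$acrophase - phi) %% 24
    errs[i] <- min(d, 24 - d)
    ps[i] <- fit$p_value
  }
  expect_lt(stats::median(errs), 0.25)
  expect_gte(mean(ps < 0.05), 0.95)
})

test_that("wrong day length is rejected", {
  expect_error(cosinor_fit(rep(1, 23)), "24")
  expect_error(cosinor_fit(c(rep(1, 23), NA)), "finite")
})

test_that("fit_window fits each complete UTC day and skips ragged edges", {
  sim <- simulate_rsv(quiet_config(seed = 19))
  ns <- stitch_segments(sim$segments)
  fits <- fit_window(ns, from = "2018-03-12", to = "2018-03-26")
  expect_identical(nrow(fits), 15L)
  expect_identical(fits$date, seq(as.Date("2018-03-12"),
                                  as.Date("2018-03-26"), by = "day"))
  # a series ending mid-day drops that day with a notice
  trunc_series <- list(time = ns$time[1:(24 * 3 + 7)],
                       values = ns$values[1:(24 * 3 + 7)])
  expect_message(f3 <- fit_window(trunc_series), "skipped incomplete")
  expect_identical(nrow(f3), 3L)
  expect_error(fit_window(ns, from = "2018-04-20", to = "2018-04-10"),
               "empty window")
})

test_that("daily acrophases track the generator's ground truth when noise is off", {
  cfg <- sim_config(noise_sd = 0, segment_scale_jitter = 0,
                    weekend_gain = 1, social_fraction = 0.6, seed = 23)
  sim <- simulate_rsv(cfg)
  ns <- stitch_segments(sim$segments)
  fits <- fit_window(ns)
  tdate <- as.Date(sim$transition)
  gt <- sim$ground_truth
  # the transition day mixes regimes; all other days must match truth
  for (i in seq_len(nrow(fits))) {
    if (fits$date[i] == tdate) next
    truth <- gt$acrophase_utc_hours[gt$date == fits$date[i]]
    d <- abs(fits$acrophase[i] - truth) %% 24
    expect_lt(min(d, 24 - d), 0.05)
  }
})

test_that("significance filter keeps p <= alpha, drops undefined acrophases", {
  fits <- data.frame(date = as.Date("2018-01-01") + 0:4,
                     acrophase = c(1, 2, NA, 4, 5),
                     p_value = c(0.01, 0.05, 0.001, 0.8, 0.049))
  out <- filter_significant(fits, alpha = 0.05)
  # brute-force oracle on the stored values, boundary p = alpha retained
  keep <- which(fits$p_value <= 0.05 & !is.na(fits$acrophase))
  expect_identical(out$date, fits$date[keep])
  expect_identical(filter_significant(out, alpha = 0.05)$date, out$date)
})
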