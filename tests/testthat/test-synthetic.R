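test_that("degenerate flat configuration yields a constant baseline series", {
  cfg <- sim_config(amplitude = 0, noise_sd = 0, weekend_gain = 1,
                    segment_scale_jitter = 0, baseline = 42)
  latent <- generate_intensity(cfg)
  expect_true(all(latent$intensity == 42))
  # max-scaling a positive constant gives all-100 segments
  segs <- segment_and_scale(latent$time, latent$intensity)
  expect_true(all(vapply(segs, function(s) all(s$values == 100), logical(1))))
})

test_that("ground-truth UTC acrophase steps by social_fraction * 60 min", {
  for (season in c("spring", "autumn")) {
    for (sf in c(0, 0.3, 0.5, 1)) {
      cfg <- sim_config(social_fraction = sf, season = season, seed = 5)
      gt <- generate_intensity(cfg)$ground_truth
      tdate <- as.Date(dst_transition(cfg$transition_year, season))
      pre <- unique(gt$acrophase_utc_hours[gt$date < tdate])
      post <- unique(gt$acrophase_utc_hours[gt$date >= tdate])
      expect_length(pre, 1L)
      expect_length(post, 1L)
      expected_step <- if (season == "spring") -sf * 60 else sf * 60
      expect_equal(phase_difference(pre, post), expected_step,
                   tolerance = 1e-12)
    }
  }
})

test_that("same seed reproduces the dataset bit for bit, different seeds differ", {
  a <- simulate_rsv(sim_config(seed = 9))
  b <- simulate_rsv(sim_config(seed = 9))
  c <- simulate_rsv(sim_config(seed = 10))
  expect_identical(a$intensity, b$intensity)
  expect_identical(lapply(a$segments, `[[`, "values"),
                   lapply(b$segments, `[[`, "values"))
  expect_false(identical(a$intensity, c$intensity))
})

test_that("segmentation layout: 7-day segments advancing by 5 days, shared instants", {
  cfg <- sim_config(days_before = 6, days_after = 5)  # 12 simulated days
  latent <- generate_intensity(cfg)
  expect_identical(length(latent$intensity), 12L * 24L)
  segs <- segment_and_scale(latent$time, latent$intensity)
  expect_length(segs, 2L)
  t1 <- segs[[1]]$start + 3600 * (0:167)
  t2 <- segs[[2]]$start + 3600 * (0:167)
  expect_identical(t1[121:168], t2[1:48])
  expect_error(segment_and_scale(latent$time[1:100], latent$intensity[1:100]),
               "shorter than 7 days")
  expect_error(segment_and_scale(latent$time[1:240], latent$intensity[1:240]),
               "7 \\+ 5k")
})

test_that("every segment peaks at exactly 100 whatever the jitter", {
  latent <- generate_intensity(sim_config(seed = 21))
  segs <- segment_and_scale(latent$time, latent$intensity,
                            segment_scale_jitter = 0.5, seed = 3)
  expect_true(all(vapply(segs, function(s) max(s$values) == 100, logical(1))))
})

test_that("without noise or jitter, un-scaling by the max recovers intensity up to rounding", {
  cfg <- sim_config(noise_sd = 0, segment_scale_jitter = 0)
  latent <- generate_intensity(cfg)
  segs <- segment_and_scale(latent$time, latent$intensity)
  for (k in seq_along(segs)) {
    idx <- (k - 1) * 120 + seq_len(168)
    rescaled <- latent$intensity[idx] / max(latent$intensity[idx]) * 100
    expect_true(max(abs(segs[[k]]$values - rescaled)) <= 0.5)
  }
})

test_that("weekend gain and event spikes act on the configured local days", {
  spike_day <- as.Date("2018-03-20")
  cfg <- sim_config(amplitude = 0, noise_sd = 0, weekend_gain = 2,
                    segment_scale_jitter = 0, baseline = 10,
                    event_spikes = data.frame(date = spike_day, gain = 3))
  latent <- generate_intensity(cfg)
  offset <- ifelse(latent$time < latent$transition, 1, 2)
  local_date <- as.Date(latent$time + offset * 3600, tz = "UTC")
  wd <- format(local_date, "%u")
  expect_true(all(latent$intensity[wd %in% c("6", "7")] == 20))
  expect_true(all(latent$intensity[local_date == spike_day] == 30))
  expect_true(all(latent$intensity[wd %in% as.character(1:5) &
                                     local_date != spike_day] == 10))
})

test_that("simulated datasets round-trip through a directory of CSVs", {
  sim <- simulate_rsv(sim_config(seed = 2))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  files <- sort(list.files(dir, pattern = "^term_IT_.*\\.csv$",
                           full.names = TRUE))
  expect_length(files, length(sim$segments))
  back <- lapply(files, read_rsv_segment)
  expect_identical(lapply(back, `[[`, "values"),
                   lapply(sim$segments, `[[`, "values"))
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_identical(nrow(gt), nrow(sim$ground_truth))
})
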