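start0 <- as.POSIXct("2018-03-10 00:00:00", tz = "UTC")

# two overlapping segments cut from one smooth positive series, each
# independently rescaled; values kept real (no rounding) unless asked
cut_two <- function(base, f1 = 1, f2 = 1) {
  list(rsv_segment("w", start0, base[1:168] * f1),
       rsv_segment("w", start0 + 120 * 3600, base[121:288] * f2))
}

smooth_series <- function(n = 288) {
  30 + 20 * cos(2 * pi * ((seq_len(n) - 1) %% 24 - 3) / 24) +
    5 * sin(2 * pi * (seq_len(n) - 1) / n)
}

test_that("overlap coefficient: identity, proportionality, LS-oracle agreement", {
  ref <- smooth_series()[121:168]
  expect_identical(overlap_coefficient(ref, ref), 1)
  expect_equal(overlap_coefficient(ref, ref * 0.5), 2)
  # against the brute-force least-squares ratio on jittered max-scaled data
  set.seed(31)
  for (g in c(0.4, 0.9, 1.7)) {
    inc <- ref * g
    inc_scaled <- inc / max(inc) * 100
    c_sum <- overlap_coefficient(ref, inc_scaled)
    c_ls <- ls_ratio(ref, inc_scaled)
    expect_equal(c_sum, c_ls, tolerance = 0.02)
    # both recover ref from the rescaled overlap
    expect_equal(inc_scaled * c_sum, ref, tolerance = 1e-9)
  }
})

test_that("overlap coefficient rejects bad input", {
  ref <- rep(1, 48)
  expect_error(overlap_coefficient(ref, rep(0, 48)), "degenerate")
  expect_error(overlap_coefficient(ref[1:47], ref[1:47]), "48")
  expect_error(overlap_coefficient(ref, c(rep(1, 47), -1)), "non-negative")
})

test_that("a single segment stitches to itself with coefficient 1", {
  seg <- rsv_segment("w", start0, smooth_series(168))
  ns <- stitch_segments(list(seg))
  expect_identical(ns$values, seg$values)
  expect_identical(ns$coefficients, 1)
})

test_that("stitching undoes arbitrary per-segment rescaling exactly (no rounding)", {
  base <- smooth_series()
  set.seed(7)
  for (i in 1:10) {
    f <- exp(stats::rnorm(2))
    # segment values must sit in [0,100]: rescale into range first
    f <- f / max(f * max(base)) * 99
    ns <- stitch_segments(cut_two(base, f[1], f[2]))
    ratio <- ns$values / base
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
    # the arbitrary factor is absorbed into the incoming coefficient
    expect_equal(ns$coefficients[2], f[1] / f[2], tolerance = 1e-12)
  }
})

test_that("chain consistency: stitching 1..n+1 equals extending a 1..n stitch", {
  sim <- simulate_rsv(sim_config(seed = 13))
  full <- stitch_segments(sim$segments)
  head5 <- stitch_segments(sim$segments[1:5])
  expect_equal(full$values[seq_along(head5$values)], head5$values)
  expect_equal(full$coefficients[1:5], head5$coefficients)
})

test_that("scale invariance: rescaling one input segment only moves its coefficient", {
  base <- smooth_series()
  segs <- cut_two(base, 99 / max(base), 99 / max(base))
  ns1 <- stitch_segments(segs)
  segs2 <- segs
  segs2[[2]] <- rsv_segment("w", segs[[2]]$start, segs[[2]]$values * 0.37)
  ns2 <- stitch_segments(segs2)
  expect_equal(ns1$values, ns2$values, tolerance = 1e-12)
  expect_equal(ns2$coefficients[2], ns1$coefficients[2] / 0.37,
               tolerance = 1e-12)
})

test_that("jitter-free synthetic month stitches back to intensity within 2% (rounding only)", {
  cfg <- sim_config(noise_sd = 0, segment_scale_jitter = 0, seed = 17)
  latent <- generate_intensity(cfg)
  segs <- segment_and_scale(latent$time, latent$intensity)
  ns <- stitch_segments(segs)
  # least-squares global rescaling onto the true intensity
  c_star <- ls_ratio(latent$intensity, ns$values)
  rel_err <- abs(ns$values * c_star - latent$intensity) / latent$intensity
  expect_lt(max(rel_err), 0.02)
})

test_that("misaligned or degenerate segments are reported with context", {
  base <- smooth_series()
  segs <- cut_two(base)
  segs[[2]] <- rsv_segment("w", segs[[2]]$start + 3600, segs[[2]]$values)
  expect_error(stitch_segments(segs), "exactly 48 hours")
  zero <- list(rsv_segment("w", start0, c(rep(0, 120), rep(c(0, 100), 24))),
               rsv_segment("w", start0 + 120 * 3600, rep(0, 168)))
  expect_error(stitch_segments(zero), "segments 1 and 2")
  mixed <- cut_two(base)
  mixed[[2]]$term <- "other"
  expect_error(stitch_segments(mixed), "one term")
})
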