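#' Configuration of the synthetic search-intensity world
#'
#' Defines the ground truth of a simulated study window around one DST
#' transition. The underlying (unobserved) hourly search intensity follows a
#' 24-h cosine in *local civil time*, optionally modulated at weekends and by
#' one-day event spikes, with additive Gaussian noise. At the transition the
#' civil clock jumps by 60 minutes; `social_fraction` sets how much of that
#' jump the rhythm adopts: 1 means searches track the wall clock fully (the
#' UTC peak moves by the full hour), 0 means they stay anchored to solar /
#' endogenous time (the UTC peak does not move at all).
#'
#' The resulting ground-truth UTC acrophase is piecewise constant with a
#' single step of `social_fraction * 60` minutes at the transition: an
#' advance (negative step) in spring, a delay (positive step) in autumn.
#'
#' @param baseline Mean underlying search intensity (arbitrary units, > 0).
#' @param amplitude Half peak-to-trough of the 24-h component (same units).
#' @param acrophase_local Local civil clock time (hours, 24-h dial) of the
#'   intensity peak before the transition.
#' @param social_fraction Fraction in \[0, 1\] of the 60-min civil shift
#'   adopted by the rhythm after the transition.
#' @param season `"spring"` (clocks +60 min) or `"autumn"` (clocks -60 min).
#' @param transition_year Calendar year of the transition.
#' @param weekend_gain Multiplicative level factor on local Saturdays and
#'   Sundays (1 = no weekend effect).
#' @param noise_sd Standard deviation of additive Gaussian noise on
#'   intensity.
#' @param segment_scale_jitter SD (log scale) of the per-segment lognormal
#'   factor emulating Google's independent sampling per request.
#' @param event_spikes Optional data frame with columns `date` (coercible to
#'   `Date`; local civil date) and `gain` (multiplicative factor for that
#'   day), e.g. a Halloween-like taxi surge.
#' @param days_before,days_after Days simulated on either side of the
#'   transition day (defaults 15 and 15, the analysis windows used
#'   throughout).
#' @param seed Integer RNG seed; the same seed reproduces the dataset
#'   bit for bit.
#' @param term Label attached to generated segments.
#'
#' @return An object of class `rsv_sim_config` (a validated list).
#' @seealso [simulate_rsv()]
#' @export
sim_config <- function(baseline = 50,
                       amplitude = 20,
                       acrophase_local = 3,
                       social_fraction = 1,
                       season = c("spring", "autumn"),
                       transition_year = 2018,
                       weekend_gain = 1.2,
                       noise_sd = 2,
                       segment_scale_jitter = 0.2,
                       event_spikes = NULL,
                       days_before = 15,
                       days_after = 15,
                       seed = 1L,
                       term = "term") {
  season <- match.arg(season)
  stopifnot(baseline > 0, amplitude >= 0, noise_sd >= 0, weekend_gain > 0,
            segment_scale_jitter >= 0, days_before >= 1, days_after >= 1)
  if (social_fraction < 0 || social_fraction > 1) {
    stop("`social_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(event_spikes)) {
    stopifnot(is.data.frame(event_spikes),
              all(c("date", "gain") %in% names(event_spikes)))
    event_spikes$date <- as.Date(event_spikes$date)
  }
  structure(list(
    baseline = baseline, amplitude = amplitude,
    acrophase_local = acrophase_local %% 24,
    social_fraction = social_fraction, season = season,
    transition_year = as.integer(transition_year),
    weekend_gain = weekend_gain, noise_sd = noise_sd,
    segment_scale_jitter = segment_scale_jitter,
    event_spikes = event_spikes,
    days_before = as.integer(days_before),
    days_after = as.integer(days_after),
    seed = as.integer(seed), term = as.character(term)
  ), class = "rsv_sim_config")
}

#' @export
print.rsv_sim_config <- function(x, ...) {
  cat("<rsv_sim_config>", x$term, "-", x$season, x$transition_year, "\n")
  cat(sprintf("  baseline %.3g, amplitude %.3g, local acrophase %.2f h\n",
              x$baseline, x$amplitude, x$acrophase_local))
  cat(sprintf("  social fraction %.2f, weekend gain %.2f, noise sd %.3g, segment jitter %.3g\n",
              x$social_fraction, x$weekend_gain, x$noise_sd,
              x$segment_scale_jitter))
  cat(sprintf("  %d days before + %d after the transition, seed %d\n",
              x$days_before, x$days_after, x$seed))
  invisible(x)
}

# Total simulated days: the window around the transition, extended at the
# tail so the series tiles exactly into 7-day segments advancing by 5 days
# (length 7 + 5k days).
sim_total_days <- function(config) {
  d0 <- config$days_before + 1L + config$days_after
  d0 + (-(d0 - 7L)) %% 5L
}

#' Generate the underlying hourly search intensity
#'
#' Produces the noiseless-to-noisy latent intensity series the generator is
#' built on, hour by UTC hour, together with the per-day ground-truth UTC
#' acrophase used by recovery tests. The series starts at 00:00 UTC
#' `days_before` days before the transition date and is extended past
#' `days_after` as needed so that it cuts exactly into 7-day segments with
#' 2-day overlaps.
#'
#' @param config An [sim_config()].
#' @return A list with `time` (`POSIXct`, UTC, hourly), `intensity`
#'   (non-negative numeric), `ground_truth` (data frame `date`,
#'   `acrophase_utc_hours`), and `transition` (`POSIXct`).
#' @export
generate_intensity <- function(config) {
  stopifnot(inherits(config, "rsv_sim_config"))
  transition <- dst_transition(config$transition_year, config$season)
  tdate <- as.Date(transition)
  start <- as.POSIXct(paste(tdate - config$days_before, "00:00:00"), tz = "UTC")
  n_days <- sim_total_days(config)
  time <- start + 3600 * (0:(n_days * 24L - 1L))

  offset <- local_utc_offset(time, transition, config$season)
  clock <- (as.numeric(time) / 3600 + offset) %% 24

  # local acrophase after the transition: the civil clock moved by +/-1 h;
  # the rhythm follows a fraction `social_fraction` of it in UTC, which on
  # the local dial means keeping (1 - social_fraction) of the jump.
  civil_shift <- if (config$season == "spring") 1 else -1
  phi_post_local <- config$acrophase_local +
    (1 - config$social_fraction) * civil_shift
  phi_local <- ifelse(time < transition, config$acrophase_local,
                      phi_post_local)

  local_date <- as.Date(time + offset * 3600, tz = "UTC")
  is_weekend <- format(local_date, "%u") %in% c("6", "7")
  spike <- rep(1, length(time))
  if (!is.null(config$event_spikes)) {
    for (i in seq_len(nrow(config$event_spikes))) {
      spike[local_date == config$event_spikes$date[i]] <-
        config$event_spikes$gain[i]
    }
  }

  set.seed(config$seed)
  eps <- stats::rnorm(length(time), 0, config$noise_sd)
  rhythmic <- config$baseline +
    config$amplitude * cos(2 * pi * (clock - phi_local) / 24)
  intensity <- pmax(0, rhythmic * ifelse(is_weekend, config$weekend_gain, 1) *
                      spike + eps)

  dates <- as.Date(time[seq(1, length(time), by = 24)], tz = "UTC")
  pre_acro <- (config$acrophase_local -
                 local_utc_offset(transition - 1, transition, config$season)) %% 24
  post_acro <- (phi_post_local -
                  local_utc_offset(transition + 1, transition, config$season)) %% 24
  ground_truth <- data.frame(
    date = dates,
    # the transition day (01:00 UTC switch) is counted as post
    acrophase_utc_hours = ifelse(dates < tdate, pre_acro, post_acro)
  )
  list(time = time, intensity = intensity, ground_truth = ground_truth,
       transition = transition)
}

#' Cut an intensity series into independently rescaled weekly RSV segments
#'
#' Emulates the Google Trends observation model: the series is cut into
#' consecutive 7-day segments whose starts advance by 5 days, so consecutive
#' segments share exactly 2 calendar days (48 hourly points). Each segment
#' is multiplied by its own lognormal jitter factor (Google's independent
#' sampling per request), linearly rescaled so its maximum is 100, rounded
#' to integers and clipped to \[0, 100\].
#'
#' @param time `POSIXct` vector of consecutive UTC hours.
#' @param intensity Non-negative hourly values, same length as `time`.
#' @param segment_scale_jitter SD (log scale) of the per-segment lognormal
#'   factor; 0 disables jitter.
#' @param seed Integer seed for the jitter draws; `NULL` uses the current
#'   RNG state.
#' @param term,geo Metadata for the produced segments.
#'
#' @return A list of [rsv_segment()] objects.
#' @export
segment_and_scale <- function(time, intensity, segment_scale_jitter = 0,
                              seed = NULL, term = "term", geo = "IT") {
  n <- length(intensity)
  stopifnot(length(time) == n)
  if (n < 168L) {
    stop("series shorter than 7 days cannot be segmented", call. = FALSE)
  }
  if ((n / 24 - 7) %% 5 != 0) {
    stop("series must span 7 + 5k whole days to tile into weekly segments ",
         "with 2-day overlaps (got ", n / 24, " days)", call. = FALSE)
  }
  n_seg <- (n / 24 - 7) / 5 + 1
  if (!is.null(seed)) set.seed(seed)
  jitter <- if (segment_scale_jitter > 0) {
    stats::rlnorm(n_seg, 0, segment_scale_jitter)
  } else rep(1, n_seg)
  lapply(seq_len(n_seg), function(k) {
    idx <- (k - 1) * 120 + seq_len(168)
    vals <- intensity[idx] * jitter[k]
    top <- max(vals)
    scaled <- if (top > 0) vals / top * 100 else vals
    rsv_segment(term, time[idx[1]],
                pmin(pmax(round(scaled), 0), 100), geo = geo)
  })
}

#' Simulate a full synthetic Google Trends dataset around a DST transition
#'
#' Runs [generate_intensity()] and [segment_and_scale()] under one seed and
#' bundles the observable segments with the latent intensity and the
#' ground-truth acrophase record, so recovery tests can compare estimates
#' against truth.
#'
#' @param config An [sim_config()].
#' @return An object of class `rsv_simulation`: a list with `segments`
#'   (list of [rsv_segment()]), `time`, `intensity`, `ground_truth`,
#'   `transition` and `config`.
#' @examples
#' sim <- simulate_rsv(sim_config(season = "spring", seed = 42))
#' length(sim$segments)
#' sim$ground_truth[14:18, ]
#' @export
simulate_rsv <- function(config) {
  stopifnot(inherits(config, "rsv_sim_config"))
  latent <- generate_intensity(config)
  segments <- segment_and_scale(
    latent$time, latent$intensity,
    segment_scale_jitter = config$segment_scale_jitter,
    seed = (config$seed %% 2147480000L) + 1L,
    term = config$term
  )
  structure(c(latent, list(segments = segments, config = config)),
            class = "rsv_simulation")
}

#' @export
print.rsv_simulation <- function(x, ...) {
  cat("<rsv_simulation>", x$config$term, "-", x$config$season,
      x$config$transition_year, "\n")
  cat("  transition:", format(x$transition, "%Y-%m-%d %H:%M", tz = "UTC"),
      "UTC\n")
  cat(" ", length(x$segments), "weekly segments covering",
      length(x$time) / 24, "days;",
      "ground-truth UTC acrophase step",
      sprintf("%+.1f min", 60 * diff(range(x$ground_truth$acrophase_utc_hours)) *
                ifelse(x$config$season == "spring", -1, 1)), "\n")
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Segments go to one CSV each (Google Trends hourly dialect, named
#' `{term}_{geo}_{start-date}.csv`); the ground-truth acrophase record goes
#' to `ground_truth.csv` with columns `date,acrophase_utc_hours`.
#'
#' @param sim An `rsv_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "rsv_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (seg in sim$segments) {
    write_rsv_segment(seg, file.path(dir, segment_filename(seg)))
  }
  utils::write.csv(sim$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
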