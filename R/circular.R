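#' Circular mean of clock-time phases
#'
#' Clock times live on a 24-h dial, so phases straddling midnight (say 23:30
#' and 00:30) must be averaged as directions, not numbers: each phase is
#' mapped to a unit vector, the vectors are averaged, and the direction of
#' the resultant is mapped back to hours. A linear mean of 23.5 and 0.5
#' would give noon; the circular mean correctly gives midnight.
#'
#' @param phases Numeric vector of phases in hours on the 24-h dial.
#' @return The circular mean, in \[0, 24).
#' @export
circular_mean_phase <- function(phases) {
  if (length(phases) < 1L || anyNA(phases)) {
    stop("need at least one non-missing phase", call. = FALSE)
  }
  ang <- phases * 2 * pi / 24
  s <- mean(sin(ang))
  c <- mean(cos(ang))
  if (sqrt(s^2 + c^2) < 1e-9) {
    stop("phases are perfectly dispersed around the dial: ",
         "circular mean undefined", call. = FALSE)
  }
  (atan2(s, c) * 24 / (2 * pi)) %% 24
}

#' Unwrap clock phases around a reference
#'
#' Maps each phase to its unique representative in
#' `(reference - 12, reference + 12]` hours, turning dial positions into
#' ordinary real numbers on which interval statistics (quartiles, IQR
#' fences, t-tests) are meaningful. Taking the result modulo 24 recovers
#' the input phases.
#'
#' @param phases Numeric vector of phases in hours (24-h dial).
#' @param reference Centre of the unwrapping interval, in \[0, 24).
#' @return Numeric vector of unwrapped phases (may be negative or exceed
#'   24), order preserved.
#' @export
unwrap_phases <- function(phases, reference) {
  stopifnot(is.numeric(phases), length(reference) == 1L,
            reference >= 0, reference < 24)
  off <- (phases - reference) %% 24
  off[off > 12] <- off[off > 12] - 24
  reference + off
}

#' Signed circular phase difference in minutes
#'
#' Returns the representative of `(post_mean - pre_mean) * 60` minutes in
#' `(-720, 720]`. Negative values are phase advances (the post phase is
#' earlier on the clock), positive values delays — the convention used for
#' pre/post-DST comparisons, where spring transitions produce advances and
#' autumn transitions delays. The wrap handles pairs straddling midnight
#' (23:55 pre vs 00:22 post is +27 min, not -1413).
#'
#' @param pre_mean,post_mean Mean phases in hours, in \[0, 24).
#' @return Signed difference in minutes, in `(-720, 720]`.
#' @examples
#' phase_difference(2.3, 1.3)          # -60: one-hour advance
#' phase_difference(23 + 55/60, 22/60) # +27: delay across midnight
#' @export
phase_difference <- function(pre_mean, post_mean) {
  stopifnot(is.numeric(pre_mean), is.numeric(post_mean))
  d <- (post_mean - pre_mean) * 60
  d <- ((d + 720) %% 1440) - 720
  ifelse(d <= -720, d + 1440, d)
}

#' Tukey boxplot outlier filter on the 24-h dial
#'
#' Removes phases lying outside the boxplot whiskers, i.e. beyond 1.5 times
#' the interquartile range from the quartiles. Because the data are clock
#' times, the phases are first unwrapped about their circular mean (see
#' [unwrap_phases()]); this keeps a tight cluster straddling midnight
#' together instead of splitting it into two spurious masses at 0 and 24.
#' Quartiles use linear interpolation between order statistics; points
#' exactly on a fence are kept.
#'
#' @param phases Numeric vector of phases in hours (24-h dial). With fewer
#'   than 4 points quartiles are not meaningful: the filter is skipped with
#'   a notice and everything is kept.
#' @return A list with `kept` and `removed`, both in \[0, 24) and in the
#'   original order.
#' @export
boxplot_outlier_filter <- function(phases) {
  stopifnot(is.numeric(phases), !anyNA(phases))
  if (length(phases) < 4L) {
    message("boxplot_outlier_filter: fewer than 4 phases, filter skipped")
    return(list(kept = phases %% 24, removed = numeric(0)))
  }
  u <- unwrap_phases(phases, circular_mean_phase(phases))
  q <- stats::quantile(u, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
  inside <- u >= fence[1] & u <= fence[2]
  list(kept = phases[inside] %% 24, removed = phases[!inside] %% 24)
}

#' Convert "HH:MM" clock strings to hours, and back
#'
#' @param x Character vector like `"23:39"` (for `hhmm_to_hours`) or
#'   numeric hours on the 24-h dial (for `hours_to_hhmm`).
#' @return Numeric hours, or character `"HH:MM"` (rounded to the nearest
#'   minute, wrapped to the dial).
#' @examples
#' hhmm_to_hours("02:18")
#' hours_to_hhmm(1.32)
#' @export
hhmm_to_hours <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) + as.numeric(p[2]) / 60,
         numeric(1))
}

#' @rdname hhmm_to_hours
#' @export
hours_to_hhmm <- function(x) {
  mins <- round(x * 60) %% 1440
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}
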