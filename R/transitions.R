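#' Instant of a Daylight Saving Time transition
#'
#' European DST rules place both transitions at 01:00 UTC: clocks go forward
#' on the last Sunday of March (`"spring"`) and back on the last Sunday of
#' October (`"autumn"`). This is the civil rule in force in Italy throughout
#' 2015-2020, the period the package's analyses are designed around.
#'
#' @param year Calendar year, between 2000 and 2100.
#' @param season `"spring"` (transition to DST) or `"autumn"` (back to
#'   standard time).
#'
#' @return A `POSIXct` timestamp in UTC: 01:00 on the last Sunday of the
#'   relevant month.
#'
#' @examples
#' dst_transition(2018, "spring")   # 2018-03-25 01:00 UTC
#' dst_transition(2018, "autumn")   # 2018-10-28 01:00 UTC
#' @export
dst_transition <- function(year, season = c("spring", "autumn")) {
  season <- match.arg(season)
  if (!is.numeric(year) || length(year) != 1L || is.na(year) ||
      year != trunc(year) || year < 2000 || year > 2100) {
    stop("`year` must be a single integer between 2000 and 2100", call. = FALSE)
  }
  month <- if (season == "spring") 3L else 10L
  last_sunday <- function(year, month) {
    # last day of month, then step back to the preceding (or same) Sunday
    last <- as.Date(sprintf("%d-%02d-01", year + (month == 12L),
                            if (month == 12L) 1L else month + 1L)) - 1L
    last - (as.integer(format(last, "%w")))  # %w: 0 = Sunday
  }
  day <- last_sunday(as.integer(year), month)
  as.POSIXct(paste(day, "01:00:00"), tz = "UTC")
}

# Fixed civil-clock offset from UTC in Italy: CET = UTC+1 (standard time),
# CEST = UTC+2 (DST). Vectorized over `times`; the switch happens exactly at
# `transition`.
local_utc_offset <- function(times, transition, season) {
  before <- times < transition
  if (season == "spring") ifelse(before, 1, 2) else ifelse(before, 2, 1)
}
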