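#' Reference table of mean RSV phases around the DST transitions
#'
#' The published reference values the package's phase arithmetic is checked
#' against: mean diurnal peak phase (UTC) of the relative search volume for
#' 11 Italian search queries over the 15 days before and after the
#' transitions to (spring) and from (autumn) DST, pooled over 2015-2020,
#' with the signed phase difference in minutes. Words fall into three
#' categories: sleep/health-related, medication, and random non
#' sleep/health-related.
#'
#' The printed `delta_min` of every row equals the circular signed
#' difference of the two printed mean phases, rounded to the minute; the
#' test suite re-derives all 22 values with [phase_difference()], so the
#' fixture is self-checking.
#'
#' @return A data frame with 22 rows and columns `word`, `category`
#'   (`sleep_health`, `medication`, `random`), `season` (`spring`,
#'   `autumn`), `phase_pre_hhmm`, `phase_post_hhmm` (printed clock
#'   strings), `phase_pre`, `phase_post` (hours on the 24-h dial),
#'   `delta_min` (signed minutes, negative = advance) and `p_label`
#'   (printed t-test significance).
#' @examples
#' t1 <- table1()
#' subset(t1, word == "insomnia")
#' @export
table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "rsvphase",
                      mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c(
    word = "character", category = "character", season = "character",
    phase_pre = "character", phase_post = "character",
    delta_min = "integer", p_label = "character"))
  df$phase_pre_hhmm <- df$phase_pre
  df$phase_post_hhmm <- df$phase_post
  df$phase_pre <- hhmm_to_hours(df$phase_pre_hhmm)
  df$phase_post <- hhmm_to_hours(df$phase_post_hhmm)
  df[, c("word", "category", "season", "phase_pre_hhmm", "phase_post_hhmm",
         "phase_pre", "phase_post", "delta_min", "p_label")]
}
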