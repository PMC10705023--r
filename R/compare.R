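#' A window of daily phases on one side of a DST transition
#'
#' Bundles the retained daily acrophases of one word, season, year and side
#' (pre or post transition) together with how many days were dropped by the
#' significance filter and the boxplot outlier filter.
#'
#' @param phases Numeric vector of daily acrophases in hours (24-h dial).
#' @param word,season,year,side Metadata; `year` may be an integer or
#'   `"combined"`, `side` is `"pre"` or `"post"`.
#' @param n_removed_nonsig,n_removed_outlier Counts of days removed
#'   upstream.
#' @return An object of class `phase_window`.
#' @export
phase_window <- function(phases, word = "term",
                         season = c("spring", "autumn"),
                         year = "combined", side = c("pre", "post"),
                         n_removed_nonsig = 0L, n_removed_outlier = 0L) {
  season <- match.arg(season)
  side <- match.arg(side)
  stopifnot(is.numeric(phases), !anyNA(phases),
            n_removed_nonsig >= 0, n_removed_outlier >= 0)
  structure(list(word = word, season = season, year = year, side = side,
                 phases = phases %% 24,
                 n_removed_nonsig = as.integer(n_removed_nonsig),
                 n_removed_outlier = as.integer(n_removed_outlier)),
            class = "phase_window")
}

#' @export
print.phase_window <- function(x, ...) {
  cat(sprintf("<phase_window> %s %s %s (%s): %d days, mean %s\n",
              x$word, x$season, as.character(x$year), x$side,
              length(x$phases),
              if (length(x$phases)) hours_to_hhmm(circular_mean_phase(x$phases))
              else "NA"))
  if (x$n_removed_nonsig + x$n_removed_outlier > 0) {
    cat(sprintf("  removed upstream: %d non-significant, %d outlier\n",
                x$n_removed_nonsig, x$n_removed_outlier))
  }
  invisible(x)
}

#' Compare pre- and post-transition phase windows
#'
#' Computes the circular mean phase of each side, the signed circular
#' difference in minutes (negative = advance), and a two-tailed unpaired
#' Student t-test (classic equal-variance form) on the daily phases after
#' unwrapping both samples about their pooled circular mean. With fewer
#' than 2 phases on a side the t-test is undefined and `p_value` is
#' returned as `NA` with a notice.
#'
#' @param pre,post [phase_window()] objects (or bare numeric phase vectors,
#'   which are wrapped with default metadata) for the same word, season and
#'   year.
#' @return An object of class `transition_comparison`: word, season, year,
#'   `mean_phase_pre`, `mean_phase_post` (hours), `delta_minutes`,
#'   `p_value`, `n_pre`, `n_post`.
#' @examples
#' pre <- phase_window(c(2.1, 2.3, 2.2, 1.9), side = "pre")
#' post <- phase_window(c(1.3, 1.1, 1.2, 1.4), side = "post")
#' compare_windows(pre, post)
#' @export
compare_windows <- function(pre, post) {
  if (!inherits(pre, "phase_window")) pre <- phase_window(pre, side = "pre")
  if (!inherits(post, "phase_window")) post <- phase_window(post, side = "post")
  if (!length(pre$phases) || !length(post$phases)) {
    stop("both windows must contain at least one phase", call. = FALSE)
  }
  if (!identical(pre$word, post$word) || !identical(pre$season, post$season) ||
      !identical(pre$year, post$year)) {
    stop("pre and post windows must describe the same word, season and year",
         call. = FALSE)
  }
  mean_pre <- circular_mean_phase(pre$phases)
  mean_post <- circular_mean_phase(post$phases)
  delta <- phase_difference(mean_pre, mean_post)

  if (length(pre$phases) < 2L || length(post$phases) < 2L) {
    message("compare_windows: a side has fewer than 2 phases, ",
            "t-test undefined")
    p <- NA_real_
  } else {
    pooled_ref <- circular_mean_phase(c(pre$phases, post$phases))
    a <- unwrap_phases(pre$phases, pooled_ref)
    b <- unwrap_phases(post$phases, pooled_ref)
    df <- length(a) + length(b) - 2
    pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
    se <- sqrt(pooled_var * (1 / length(a) + 1 / length(b)))
    p <- if (se == 0) {
      # no within-group spread: identical means are indistinguishable
      # (p = 1), different means are separated with certainty (p = 0)
      if (mean(a) == mean(b)) 1 else 0
    } else {
      2 * stats::pt(-abs((mean(a) - mean(b)) / se), df)
    }
  }
  structure(list(word = pre$word, season = pre$season, year = pre$year,
                 mean_phase_pre = mean_pre, mean_phase_post = mean_post,
                 delta_minutes = delta, p_value = p,
                 n_pre = length(pre$phases), n_post = length(post$phases)),
            class = "transition_comparison")
}

#' @export
print.transition_comparison <- function(x, ...) {
  cat(sprintf("<transition_comparison> %s %s %s\n",
              x$word, x$season, as.character(x$year)))
  cat(sprintf("  phase pre %s, post %s  (delta %+.1f min, %s)\n",
              hours_to_hhmm(x$mean_phase_pre),
              hours_to_hhmm(x$mean_phase_post), x$delta_minutes,
              if (is.na(x$p_value)) "p NA"
              else sprintf("p = %.3g", x$p_value)))
  cat(sprintf("  n = %d pre, %d post\n", x$n_pre, x$n_post))
  invisible(x)
}

#' Across-year trend in phase
#'
#' Tests whether the daily phase of a given side (pre or post) changes
#' across study years, as reported for the progressive phase anticipation
#' of search timing. Two complementary summaries are returned: a one-way
#' ANOVA of the unwrapped daily phases across years (F and p), and an
#' ordinary least-squares slope of phase on calendar year with its t-test
#' p-value, expressed in minutes per year. Zero-variance (degenerate)
#' input is flagged rather than erroring.
#'
#' @param yearly Named list mapping year (as name) to a numeric vector of
#'   daily phases in hours; at least 3 years with at least 2 phases each.
#' @param side `"pre"` or `"post"`, carried as metadata.
#' @return An object of class `year_trend`: `anova_f`, `anova_p`,
#'   `slope_min_per_year`, `slope_p`, `n_years`, `degenerate`, `side`.
#' @export
year_trend <- function(yearly, side = c("pre", "post")) {
  side <- match.arg(side)
  if (length(yearly) < 3L || any(lengths(yearly) < 2L)) {
    stop("need at least 3 years with at least 2 phases each", call. = FALSE)
  }
  years <- as.numeric(names(yearly))
  if (anyNA(years)) stop("`yearly` must be named by year", call. = FALSE)
  phases <- unlist(yearly, use.names = FALSE)
  year_of <- rep(years, lengths(yearly))
  u <- unwrap_phases(phases, circular_mean_phase(phases))

  if (stats::sd(u) == 0) {
    return(structure(list(anova_f = NA_real_, anova_p = NA_real_,
                          slope_min_per_year = 0, slope_p = NA_real_,
                          n_years = length(yearly), degenerate = TRUE,
                          side = side), class = "year_trend"))
  }
  av <- stats::anova(stats::lm(u ~ factor(year_of)))
  sl <- summary(stats::lm(u ~ year_of))$coefficients
  structure(list(anova_f = av$`F value`[1], anova_p = av$`Pr(>F)`[1],
                 slope_min_per_year = sl["year_of", "Estimate"] * 60,
                 slope_p = sl["year_of", "Pr(>|t|)"],
                 n_years = length(yearly), degenerate = FALSE,
                 side = side), class = "year_trend")
}

#' @export
print.year_trend <- function(x, ...) {
  cat("<year_trend>", x$side, "window,", x$n_years, "years\n")
  if (x$degenerate) {
    cat("  degenerate: zero phase variance across all days\n")
  } else {
    cat(sprintf("  year ANOVA: F = %.3g, p = %.3g\n", x$anova_f, x$anova_p))
    cat(sprintf("  linear trend: %+.2f min/year (p = %.3g)\n",
                x$slope_min_per_year, x$slope_p))
  }
  invisible(x)
}
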