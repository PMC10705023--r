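#' Fit the full phase analysis for one word, season and year
#'
#' The end-to-end estimator the package is built around. Starting from
#' weekly RSV segments (simulated via [simulate_rsv()] or read from disk),
#' it (1) chain-normalizes the segments onto the first week's scale,
#' (2) fits a 24-h cosinor to every complete UTC day, (3) drops days whose
#' fit is not significant at `alpha`, (4) drops boxplot outliers within
#' each 15-day window, and (5) compares the circular mean phase of the
#' pre-transition window with the post-transition window (signed difference
#' in minutes, Student t-test). The transition day itself belongs to
#' neither window: the clocks change at 01:00 UTC, so that day mixes both
#' regimes.
#'
#' @param x An [sim_config()] (the synthetic world is generated under its
#'   seed) or a list of [rsv_segment()] objects.
#' @param season,year Transition season and year; taken from the config
#'   when `x` is one, required otherwise.
#' @param window_days Days in each comparison window (default 15).
#' @param alpha Significance level of the daily rhythm filter (default
#'   0.05).
#'
#' @return An object of class `dst_phase`: a list with `comparison` (a
#'   [compare_windows()] result), `pre`, `post` ([phase_window()]s),
#'   `daily_fits`, `series` (the `normalized_series`), `ground_truth`
#'   (when simulated, else `NULL`), `transition`, `word`, `season`,
#'   `year`, `window_days`, `alpha`. Methods: `print`, `summary`, `coef`,
#'   `plot`.
#' @examples
#' fit <- dst_phase_fit(sim_config(social_fraction = 1, seed = 3))
#' coef(fit)  # phase pre/post (h) and delta (min)
#' @export
dst_phase_fit <- function(x, season = NULL, year = NULL,
                          window_days = 15, alpha = 0.05) {
  ground_truth <- NULL
  if (inherits(x, "rsv_sim_config")) {
    sim <- simulate_rsv(x)
    segments <- sim$segments
    ground_truth <- sim$ground_truth
    season <- x$season
    year <- x$transition_year
    word <- x$term
  } else if (is.list(x) && length(x) &&
             inherits(x[[1]], "rsv_segment")) {
    segments <- x
    if (is.null(season) || is.null(year)) {
      stop("`season` and `year` are required when fitting raw segments",
           call. = FALSE)
    }
    word <- segments[[1]]$term
  } else {
    stop("`x` must be an rsv_sim_config or a list of rsv_segment objects",
         call. = FALSE)
  }
  transition <- dst_transition(year, season)
  tdate <- as.Date(transition)

  series <- stitch_segments(segments)
  fits <- fit_window(series)

  side_window <- function(days, side) {
    sub <- fits[fits$date %in% days, , drop = FALSE]
    sig <- filter_significant(sub, alpha)
    flt <- boxplot_outlier_filter(sig$acrophase)
    phase_window(flt$kept, word = word, season = season, year = year,
                 side = side,
                 n_removed_nonsig = nrow(sub) - nrow(sig),
                 n_removed_outlier = length(flt$removed))
  }
  pre <- side_window(seq(tdate - window_days, tdate - 1, by = "day"), "pre")
  post <- side_window(seq(tdate + 1, tdate + window_days, by = "day"), "post")
  comparison <- compare_windows(pre, post)

  structure(list(comparison = comparison, pre = pre, post = post,
                 daily_fits = fits, series = series,
                 ground_truth = ground_truth, transition = transition,
                 word = word, season = season, year = year,
                 window_days = window_days, alpha = alpha),
            class = "dst_phase")
}

#' @export
print.dst_phase <- function(x, ...) {
  cat(sprintf("DST phase analysis: '%s', %s %s\n", x$word, x$season, x$year))
  cat("  transition:", format(x$transition, "%Y-%m-%d %H:%M", tz = "UTC"),
      "UTC;", x$window_days, "days per window\n")
  cat(sprintf("  mean phase pre %s UTC, post %s UTC\n",
              hours_to_hhmm(x$comparison$mean_phase_pre),
              hours_to_hhmm(x$comparison$mean_phase_post)))
  cat(sprintf("  phase %s of %.0f min (%s)\n",
              if (x$comparison$delta_minutes <= 0) "advance" else "delay",
              abs(x$comparison$delta_minutes),
              if (is.na(x$comparison$p_value)) "t-test undefined"
              else sprintf("t-test p = %.3g", x$comparison$p_value)))
  invisible(x)
}

#' @export
summary.dst_phase <- function(object, ...) {
  print(object)
  cat(sprintf("  days: %d pre (%d non-sig, %d outlier removed), %d post (%d, %d)\n",
              object$comparison$n_pre, object$pre$n_removed_nonsig,
              object$pre$n_removed_outlier, object$comparison$n_post,
              object$post$n_removed_nonsig, object$post$n_removed_outlier))
  if (!is.null(object$ground_truth)) {
    gt <- object$ground_truth
    step <- phase_difference(gt$acrophase_utc_hours[1],
                             gt$acrophase_utc_hours[nrow(gt)])
    cat(sprintf("  ground-truth UTC phase step: %+.1f min (estimated %+.1f)\n",
                step, object$comparison$delta_minutes))
  }
  invisible(object)
}

#' @export
coef.dst_phase <- function(object, ...) {
  c(phase_pre = object$comparison$mean_phase_pre,
    phase_post = object$comparison$mean_phase_post,
    delta_min = object$comparison$delta_minutes)
}

#' @export
plot.dst_phase <- function(x, ...) {
  f <- x$daily_fits
  tdate <- as.Date(x$transition)
  rel <- as.numeric(f$date - tdate)
  ref <- circular_mean_phase(f$acrophase[!is.na(f$acrophase)])
  ph <- unwrap_phases(f$acrophase, ref)
  graphics::plot(rel, ph, xlab = "days from transition",
                 ylab = "acrophase (h, UTC, unwrapped)",
                 main = sprintf("'%s' %s %s", x$word, x$season, x$year),
                 pch = ifelse(f$p_value <= x$alpha, 19, 1), ...)
  graphics::abline(v = 0, lty = 2)
  graphics::segments(-x$window_days, unwrap_phases(
    x$comparison$mean_phase_pre, ref), -1,
    unwrap_phases(x$comparison$mean_phase_pre, ref), col = "steelblue",
    lwd = 2)
  graphics::segments(1, unwrap_phases(x$comparison$mean_phase_post, ref),
                     x$window_days,
                     unwrap_phases(x$comparison$mean_phase_post, ref),
                     col = "firebrick", lwd = 2)
  invisible(x)
}

#' Run the phase-comparison pipeline over a synthetic study
#'
#' Maps [dst_phase_fit()] over a list of simulation configs (one per word x
#' season x year), then adds, for every word x season, a `"combined"` row
#' that pools all retained daily phases across that word's years — the
#' shape of a per-word/season results table with yearly and combined
#' entries.
#'
#' @param configs List of [sim_config()] objects.
#' @param window_days,alpha Passed to [dst_phase_fit()].
#' @param categories Optional named character vector mapping word to
#'   category label.
#' @return A data frame of class `dst_phase_table` with columns `word`,
#'   `category`, `season`, `scope` (year or `"combined"`),
#'   `phase_pre_hhmm`, `phase_post_hhmm`, `phase_pre_h`, `phase_post_h`,
#'   `delta_min`, `p_value`, `n_pre`, `n_post`. The per-stage drop counts
#'   are attached as `attr(, "drop_log")` and the individual `dst_phase`
#'   fits as `attr(, "fits")`.
#' @export
run_pipeline <- function(configs, window_days = 15, alpha = 0.05,
                         categories = NULL) {
  stopifnot(is.list(configs), length(configs) >= 1,
            all(vapply(configs, inherits, logical(1), "rsv_sim_config")))
  fits <- lapply(configs, dst_phase_fit, window_days = window_days,
                 alpha = alpha)
  cat_of <- function(word) {
    if (!is.null(categories) && word %in% names(categories))
      categories[[word]] else NA_character_
  }
  row_of <- function(cmp, scope) {
    data.frame(word = cmp$word, category = cat_of(cmp$word),
               season = cmp$season, scope = as.character(scope),
               phase_pre_hhmm = hours_to_hhmm(cmp$mean_phase_pre),
               phase_post_hhmm = hours_to_hhmm(cmp$mean_phase_post),
               phase_pre_h = cmp$mean_phase_pre,
               phase_post_h = cmp$mean_phase_post,
               delta_min = cmp$delta_minutes, p_value = cmp$p_value,
               n_pre = cmp$n_pre, n_post = cmp$n_post)
  }
  keys <- vapply(fits, function(f) paste(f$word, f$season, sep = "\r"),
                 character(1))
  rows <- list()
  logs <- list()
  for (key in unique(keys)) {
    group <- fits[keys == key]
    for (f in group) {
      rows[[length(rows) + 1L]] <- row_of(f$comparison, f$year)
      logs[[length(logs) + 1L]] <- data.frame(
        word = f$word, season = f$season, year = f$year,
        side = c("pre", "post"),
        n_removed_nonsig = c(f$pre$n_removed_nonsig,
                             f$post$n_removed_nonsig),
        n_removed_outlier = c(f$pre$n_removed_outlier,
                              f$post$n_removed_outlier),
        n_retained = c(f$comparison$n_pre, f$comparison$n_post))
    }
    pool <- function(side) {
      phase_window(
        unlist(lapply(group, function(f) f[[side]]$phases)),
        word = group[[1]]$word, season = group[[1]]$season,
        year = "combined", side = side,
        n_removed_nonsig = sum(vapply(group, function(f)
          f[[side]]$n_removed_nonsig, integer(1))),
        n_removed_outlier = sum(vapply(group, function(f)
          f[[side]]$n_removed_outlier, integer(1))))
    }
    rows[[length(rows) + 1L]] <-
      row_of(compare_windows(pool("pre"), pool("post")), "combined")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "drop_log") <- do.call(rbind, logs)
  attr(out, "fits") <- fits
  class(out) <- c("dst_phase_table", "data.frame")
  out
}

#' @export
print.dst_phase_table <- function(x, ...) {
  cat("Phase comparison around DST transitions (",
      sum(x$scope != "combined"), " word-years, ",
      sum(x$scope == "combined"), " combined rows)\n", sep = "")
  df <- as.data.frame(x)[, c("word", "season", "scope", "phase_pre_hhmm",
                             "phase_post_hhmm", "delta_min", "p_value",
                             "n_pre", "n_post")]
  df$p_value <- signif(df$p_value, 3)
  df$delta_min <- round(df$delta_min, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline results table to CSV
#'
#' @param x A `dst_phase_table`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_phase_table <- function(x, file) {
  df <- as.data.frame(x)[, c("word", "category", "season", "scope",
                             "phase_pre_hhmm", "phase_post_hhmm",
                             "delta_min", "p_value", "n_pre", "n_post")]
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
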