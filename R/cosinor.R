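#' Single-harmonic cosinor fit of one calendar day
#'
#' Fits `y_t = M + A * cos(2*pi*(t - phi)/24)` to 24 hourly values by least
#' squares, via the linear parameterization
#' `y_t = M + b1*cos(2*pi*t/24) + b2*sin(2*pi*t/24)` with `A = sqrt(b1^2 +
#' b2^2)` and acrophase `phi = atan2(b2, b1) * 24/(2*pi) mod 24`. This is
#' the standard chronobiology model for a fixed 24-h period: `M` is the
#' mesor (rhythm-adjusted mean), `A` the amplitude and `phi` the clock time
#' of the fitted peak.
#'
#' Rhythmicity is tested with the overall regression F statistic,
#' `F = (SS_model/2) / (SS_residual/21)` on (2, 21) degrees of freedom
#' (null: `A = 0`). The fit also reports the Pearson correlation between
#' fitted and observed values, the oscillation range (peak-to-trough,
#' `2*A`) and the Rhythmicity Index `RI = r * 2*A`, a rhythm-quality score
#' that grows with both how reproducible and how large the oscillation is.
#'
#' A constant day is degenerate: it returns amplitude 0, `p = 1` and an
#' undefined (`NA`) acrophase, so downstream significance filtering removes
#' it rather than erroring.
#'
#' @param y Exactly 24 finite hourly values, `y[1]` at hour 0 of the day.
#' @param date Optional calendar date (`Date`) the day belongs to.
#'
#' @return An object of class `cosinor`: a list with `mesor`, `amplitude`,
#'   `acrophase` (hours in \[0, 24) or `NA`), `p_value`, `pearson_r`,
#'   `oscillation_range`, `rhythmicity_index`, `n_points`, `coefficients`
#'   (`mesor`, `beta_cos`, `beta_sin`), `fitted.values`, `residuals`, `y`
#'   and `date`. Supported methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' y <- 10 + 3 * cos(2 * pi * (0:23 - 5) / 24)
#' fit <- cosinor_fit(y)
#' coef(fit)
#' fit$acrophase   # 5
#' @export
cosinor_fit <- function(y, date = NULL) {
  if (length(y) != 24L || !is.numeric(y) || anyNA(y) || any(!is.finite(y))) {
    stop("`y` must be exactly 24 finite hourly values", call. = FALSE)
  }
  t <- 0:23
  w <- 2 * pi * t / 24
  X <- cbind(1, cos(w), sin(w))
  # orthogonal design over a full day: solve() is exact and cheap
  beta <- drop(solve(crossprod(X), crossprod(X, y)))
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  ss_model <- sum((fitted - mean(y))^2)
  ss_res <- sum(resid^2)

  amplitude <- sqrt(beta[2]^2 + beta[3]^2)
  degenerate <- ss_model <= .Machine$double.eps * max(1, sum(y^2))
  acrophase <- if (degenerate) NA_real_ else
    (atan2(beta[3], beta[2]) * 24 / (2 * pi)) %% 24
  if (degenerate) {
    p_value <- 1
    r <- 0
    amplitude <- 0
  } else if (ss_res <= .Machine$double.eps * max(1, sum(y^2))) {
    p_value <- 0  # perfect fit
    r <- 1
  } else {
    f_stat <- (ss_model / 2) / (ss_res / 21)
    p_value <- stats::pf(f_stat, 2, 21, lower.tail = FALSE)
    r <- stats::cor(fitted, y)
  }

  structure(list(
    mesor = beta[1], amplitude = amplitude, acrophase = acrophase,
    p_value = p_value, pearson_r = r,
    oscillation_range = 2 * amplitude,
    rhythmicity_index = r * 2 * amplitude,
    n_points = 24L,
    coefficients = c(mesor = beta[1], beta_cos = beta[2], beta_sin = beta[3]),
    fitted.values = fitted, residuals = resid, y = y,
    date = if (is.null(date)) NULL else as.Date(date)
  ), class = "cosinor")
}

#' @export
print.cosinor <- function(x, digits = 4, ...) {
  cat("24-h cosinor fit",
      if (!is.null(x$date)) paste0("(", format(x$date), ")"), "\n")
  cat(sprintf("  mesor %.*g, amplitude %.*g, acrophase %s\n",
              digits, x$mesor, digits, x$amplitude,
              if (is.na(x$acrophase)) "undefined"
              else sprintf("%.*g h", digits, x$acrophase)))
  cat(sprintf("  p = %.3g, r = %.3f, RI = %.*g\n",
              x$p_value, x$pearson_r, digits, x$rhythmicity_index))
  invisible(x)
}

#' @export
summary.cosinor <- function(object, ...) {
  out <- c(mesor = object$mesor, amplitude = object$amplitude,
           acrophase = object$acrophase, p_value = object$p_value,
           pearson_r = object$pearson_r,
           oscillation_range = object$oscillation_range,
           rhythmicity_index = object$rhythmicity_index)
  class(out) <- "summary.cosinor"
  out
}

#' @export
print.summary.cosinor <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' @export
coef.cosinor <- function(object, ...) object$coefficients

#' Predicted cosinor curve
#'
#' @param object A [cosinor_fit()].
#' @param hours Hour offsets from the start of the day at which to evaluate
#'   the fitted curve (default the 24 observation hours; fractions allowed).
#' @param ... Unused.
#' @return Numeric vector of predicted values.
#' @export
predict.cosinor <- function(object, hours = 0:23, ...) {
  w <- 2 * pi * hours / 24
  b <- object$coefficients
  drop(b[1] + b[2] * cos(w) + b[3] * sin(w))
}

#' @export
residuals.cosinor <- function(object, ...) object$residuals

#' @export
fitted.cosinor <- function(object, ...) object$fitted.values

#' @export
plot.cosinor <- function(x, ...) {
  hours <- seq(0, 23.9, by = 0.1)
  graphics::plot(0:23, x$y, xlab = "hour of day (UTC)", ylab = "value",
                 main = if (!is.null(x$date)) format(x$date) else
                   "24-h cosinor fit", ...)
  graphics::lines(hours, predict(x, hours), col = "steelblue", lwd = 2)
  if (!is.na(x$acrophase)) {
    graphics::abline(v = x$acrophase, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Fit a cosinor to every calendar day of a normalized series
#'
#' Cuts the series into whole UTC days and fits [cosinor_fit()] to each
#' complete one. Incomplete edge days (fewer than 24 hours covered) are
#' skipped with a notice.
#'
#' @param series A `normalized_series` from [stitch_segments()], or any
#'   list with `POSIXct` `time` and numeric `values` elements.
#' @param from,to First and last calendar day (coercible to `Date`,
#'   inclusive) to fit; default spans the whole series.
#'
#' @return A data frame of class `daily_fits` with one row per fitted day:
#'   `date`, `mesor`, `amplitude`, `acrophase`, `p_value`, `pearson_r`,
#'   `oscillation_range`, `rhythmicity_index`, `n_points`.
#' @export
fit_window <- function(series, from = NULL, to = NULL) {
  time <- series$time
  values <- series$values
  dates <- as.Date(time, tz = "UTC")
  from <- if (is.null(from)) min(dates) else as.Date(from)
  to <- if (is.null(to)) max(dates) else as.Date(to)
  if (from > to) stop("empty window: `from` is after `to`", call. = FALSE)
  days <- seq(from, to, by = "day")
  rows <- vector("list", length(days))
  skipped <- character()
  for (i in seq_along(days)) {
    idx <- which(dates == days[i])
    if (length(idx) != 24L) {
      skipped <- c(skipped, format(days[i]))
      next
    }
    # order within the day is already hourly-ascending by construction
    f <- cosinor_fit(values[idx], date = days[i])
    rows[[i]] <- data.frame(
      date = days[i], mesor = f$mesor, amplitude = f$amplitude,
      acrophase = f$acrophase, p_value = f$p_value,
      pearson_r = f$pearson_r, oscillation_range = f$oscillation_range,
      rhythmicity_index = f$rhythmicity_index, n_points = f$n_points
    )
  }
  if (length(skipped)) {
    message("fit_window: skipped incomplete day(s) ",
            paste(skipped, collapse = ", "))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    stop("window contains no complete UTC day", call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("daily_fits", "data.frame")
  out
}

#' Drop days whose rhythm fit is not significant
#'
#' Keeps exactly the days with fit `p_value <= alpha` and a defined
#' acrophase, preserving order. Days with `p` exactly at `alpha` are
#' retained (the removal rule is `p > alpha`).
#'
#' @param fits A `daily_fits` data frame from [fit_window()].
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return The filtered `daily_fits` data frame.
#' @export
filter_significant <- function(fits, alpha = 0.05) {
  stopifnot(is.data.frame(fits), alpha > 0, alpha < 1)
  keep <- fits$p_value <= alpha & !is.na(fits$acrophase)
  out <- fits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write per-day cosinor fits to CSV
#'
#' @param fits A `daily_fits` data frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_daily_fits <- function(fits, file) {
  df <- fits
  names(df)[names(df) == "acrophase"] <- "acrophase_h"
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
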