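#' Normalization coefficient from a 48-hour overlap
#'
#' Two consecutive weekly RSV segments share their two boundary calendar
#' days. Because each segment sits on its own private 0-100 scale, the ratio
#' of the overlapping days is what links the scales: this function returns
#' `sum(reference_overlap) / sum(incoming_overlap)`, the factor that
#' expresses the incoming segment on the reference scale. The sum ratio
#' (equivalently, the ratio of the 48-h means) is used rather than a mean of
#' pointwise ratios, which blows up on near-zero night-time hours.
#'
#' @param reference_overlap Numeric vector of 48 hourly values on the
#'   reference scale.
#' @param incoming_overlap Numeric vector of the same 48 instants as seen by
#'   the incoming segment.
#' @return A positive scalar coefficient.
#' @export
overlap_coefficient <- function(reference_overlap, incoming_overlap) {
  if (length(reference_overlap) != 48L || length(incoming_overlap) != 48L) {
    stop("overlaps must cover exactly 48 hourly points", call. = FALSE)
  }
  if (anyNA(reference_overlap) || anyNA(incoming_overlap) ||
      any(reference_overlap < 0) || any(incoming_overlap < 0)) {
    stop("overlap values must be finite and non-negative", call. = FALSE)
  }
  denom <- sum(incoming_overlap)
  if (denom <= 0) {
    stop("degenerate overlap: incoming segment sums to zero, ",
         "normalization coefficient undefined", call. = FALSE)
  }
  sum(reference_overlap) / denom
}

#' Chain-normalize overlapping RSV segments onto the first segment's scale
#'
#' Implements the stitching step of the analysis: the first week is the
#' reference (coefficient 1); every later segment is rescaled by the ratio
#' of the shared two days as seen on the already-normalized series versus on
#' the segment's own scale, so coefficients chain multiplicatively back to
#' the reference. On shared days the earlier (already normalized) values are
#' retained; the incoming overlap is used only to estimate the coefficient.
#'
#' @param segments List of [rsv_segment()] objects with identical `term` and
#'   `geo`, each starting exactly 5 days after its predecessor (a 48-hour
#'   overlap).
#' @return An object of class `normalized_series`: list with `term`, `geo`,
#'   `start`, `time` (`POSIXct`, hourly, UTC), `values` (non-negative
#'   reals), `coefficients` (one per segment, first = 1) and
#'   `segment_starts`.
#' @examples
#' sim <- simulate_rsv(sim_config(seed = 7))
#' ns <- stitch_segments(sim$segments)
#' ns$coefficients
#' @export
stitch_segments <- function(segments) {
  if (length(segments) < 1L) {
    stop("need at least one segment", call. = FALSE)
  }
  stopifnot(all(vapply(segments, inherits, logical(1), "rsv_segment")))
  term <- segments[[1]]$term
  geo <- segments[[1]]$geo
  if (!all(vapply(segments, function(s) identical(s$term, term) &&
                    identical(s$geo, geo), logical(1)))) {
    stop("all segments must share one term and geo", call. = FALSE)
  }
  starts <- do.call(c, lapply(segments, `[[`, "start"))
  if (length(segments) > 1L &&
      any(diff(as.numeric(starts)) != 5 * 86400)) {
    bad <- which(diff(as.numeric(starts)) != 5 * 86400)[1]
    stop("segments ", bad, " and ", bad + 1L,
         " do not overlap by exactly 48 hours", call. = FALSE)
  }

  values <- segments[[1]]$values
  coefficients <- 1
  for (k in seq_along(segments)[-1]) {
    ref_overlap <- values[(length(values) - 47L):length(values)]
    inc <- segments[[k]]$values
    ck <- tryCatch(
      overlap_coefficient(ref_overlap, inc[1:48]),
      error = function(e) {
        stop("stitching segments ", k - 1L, " and ", k, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    values <- c(values, inc[49:168] * ck)
    coefficients <- c(coefficients, ck)
  }
  time <- segments[[1]]$start + 3600 * (seq_along(values) - 1L)
  structure(list(term = term, geo = geo, start = segments[[1]]$start,
                 time = time, values = values,
                 coefficients = coefficients, segment_starts = starts),
            class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat("<normalized_series>", x$term, " geo:", x$geo, "\n")
  cat("  ", length(x$values), " hourly values from ",
      format(x$start, "%Y-%m-%d %H:%M", tz = "UTC"), " UTC (",
      length(x$values) / 24, " days, ", length(x$coefficients),
      " segments)\n", sep = "")
  cat("  coefficients:",
      paste(sprintf("%.4g", x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.normalized_series <- function(x, ...) {
  data.frame(datetime = x$time, rsv_normalized = x$values)
}

#' Write a normalized series (and its coefficients) to CSV
#'
#' Values are written at full precision as `datetime,rsv_normalized`; the
#' per-segment normalization coefficients go to a sidecar CSV
#' (`segment_start,coefficient`).
#'
#' @param x A `normalized_series`.
#' @param file Output CSV path.
#' @param coef_file Optional sidecar path; default replaces the extension
#'   with `_coefficients.csv`.
#' @return `file`, invisibly.
#' @export
write_normalized_series <- function(x, file, coef_file = NULL) {
  stopifnot(inherits(x, "normalized_series"))
  df <- data.frame(
    datetime = format(x$time, "%Y-%m-%dT%H:00", tz = "UTC"),
    rsv_normalized = format(x$values, digits = 17, trim = TRUE,
                            scientific = FALSE)
  )
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  if (is.null(coef_file)) {
    coef_file <- sub("\\.csv$", "_coefficients.csv", file)
  }
  utils::write.csv(
    data.frame(segment_start = format(x$segment_starts, "%Y-%m-%dT%H:00",
                                      tz = "UTC"),
               coefficient = format(x$coefficients, digits = 17,
                                    trim = TRUE, scientific = FALSE)),
    coef_file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
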