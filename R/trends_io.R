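#' One week of hourly relative search volume on its own 0-100 scale
#'
#' Google Trends delivers hourly data in windows whose values are rescaled so
#' that the window maximum is 100. An `rsv_segment` holds one such 7-day
#' window: 168 consecutive hourly values, each on the segment's private
#' relative scale.
#'
#' @param term Search query the segment belongs to.
#' @param geo Location code (default `"IT"`).
#' @param start `POSIXct` (UTC) of the first hour; must fall on a whole hour.
#' @param values Numeric vector of 168 hourly values in \[0, 100\].
#'
#' @return An object of class `rsv_segment`: a list with fields `term`,
#'   `geo`, `start` and `values`.
#' @seealso [read_rsv_segment()], [write_rsv_segment()], [stitch_segments()]
#' @export
rsv_segment <- function(term, start, values, geo = "IT") {
  if (!inherits(start, "POSIXct")) {
    start <- as.POSIXct(start, tz = "UTC")
  }
  attr(start, "tzone") <- "UTC"
  if (as.numeric(start) %% 3600 != 0) {
    stop("`start` must fall on a whole hour", call. = FALSE)
  }
  if (length(values) != 168L) {
    stop("an RSV segment holds exactly 168 hourly values, got ",
         length(values), call. = FALSE)
  }
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0) || any(values > 100)) {
    stop("segment values must be finite and within [0, 100]", call. = FALSE)
  }
  structure(list(term = as.character(term), geo = as.character(geo),
                 start = start, values = values),
            class = "rsv_segment")
}

#' @export
print.rsv_segment <- function(x, ...) {
  cat("<rsv_segment> term:", x$term, " geo:", x$geo, "\n")
  cat("  start:", format(x$start, "%Y-%m-%d %H:%M", tz = "UTC"),
      "UTC;", length(x$values), "hourly values, max", max(x$values), "\n")
  invisible(x)
}

segment_times <- function(segment) {
  segment$start + 3600 * (seq_along(segment$values) - 1L)
}

#' Read one Google Trends hourly segment from CSV
#'
#' Parses the hourly-export dialect used throughout the package: a header
#' `datetime,rsv` followed by 168 rows of `YYYY-MM-DDTHH:00` timestamps
#' (UTC, no zone suffix) and integer values in \[0, 100\]. The timestamps
#' are checked to be contiguous whole hours; the first gap or duplicate is
#' named in the error.
#'
#' @param file Path or connection to read from.
#' @param term,geo Metadata to attach; when `file` is a path matching the
#'   `{term}_{geo}_{date}.csv` naming scheme and these are missing, they are
#'   recovered from the filename.
#'
#' @return An [rsv_segment()].
#' @export
read_rsv_segment <- function(file, term = NULL, geo = NULL) {
  df <- utils::read.csv(file, colClasses = "character")
  if (!identical(names(df), c("datetime", "rsv"))) {
    stop("expected header 'datetime,rsv', got '",
         paste(names(df), collapse = ","), "'", call. = FALSE)
  }
  if (nrow(df) != 168L) {
    stop("expected 168 hourly rows, got ", nrow(df), call. = FALSE)
  }
  stamps <- as.POSIXct(df$datetime, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  if (anyNA(stamps)) {
    stop("unparseable timestamp: '", df$datetime[which(is.na(stamps))[1]], "'",
         call. = FALSE)
  }
  step <- diff(as.numeric(stamps))
  if (any(step != 3600)) {
    bad <- which(step != 3600)[1]
    stop("timestamps not contiguous hourly: break after ",
         format(stamps[bad], "%Y-%m-%dT%H:%M"), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df$rsv))
  if (anyNA(vals) || any(vals != trunc(vals))) {
    stop("RSV values must be integers", call. = FALSE)
  }
  if (any(vals < 0 | vals > 100)) {
    stop("RSV value out of range [0, 100]: ", vals[which(vals < 0 | vals > 100)[1]],
         call. = FALSE)
  }
  if (is.null(term) || is.null(geo)) {
    guess <- if (is.character(file)) {
      sub("\\.csv$", "", basename(file))
    } else ""
    parts <- strsplit(guess, "_", fixed = TRUE)[[1]]
    if (is.null(term)) term <- if (length(parts) >= 3) parts[1] else "term"
    if (is.null(geo))  geo  <- if (length(parts) >= 3) parts[2] else "IT"
  }
  rsv_segment(term, stamps[1], vals, geo = geo)
}

#' Write one segment in the Google Trends hourly CSV dialect
#'
#' Inverse of [read_rsv_segment()]: `read_rsv_segment(write_rsv_segment(s))`
#' reproduces `s` exactly. Timestamps are serialized as `YYYY-MM-DDTHH:00`
#' and documented as UTC; values are written as integers.
#'
#' @param segment An [rsv_segment()] with integer values.
#' @param file Path or connection to write to. Defaults to the canonical
#'   `{term}_{geo}_{start-date}.csv` name in the current directory.
#' @return The path or connection, invisibly.
#' @export
write_rsv_segment <- function(segment, file = segment_filename(segment)) {
  stopifnot(inherits(segment, "rsv_segment"))
  if (any(segment$values != round(segment$values))) {
    stop("only integer-valued segments can be serialized", call. = FALSE)
  }
  df <- data.frame(
    datetime = format(segment_times(segment), "%Y-%m-%dT%H:00", tz = "UTC"),
    rsv = format(as.integer(round(segment$values)), trim = TRUE, scientific = FALSE)
  )
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Canonical file name for a segment
#'
#' @param segment An [rsv_segment()].
#' @return `"{term}_{geo}_{start-date}.csv"`.
#' @export
segment_filename <- function(segment) {
  sprintf("%s_%s_%s.csv", gsub("\\s+", "-", segment$term), segment$geo,
          format(segment$start, "%Y-%m-%d", tz = "UTC"))
}
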