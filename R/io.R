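#' Read a time series from disk
#'
#' Accepts three plain-text layouts: a CSV with a header and `time,value`
#' columns (time either numeric minutes or ISO-8601 timestamps), a CSV with
#' a single `value` column, or a plain text file with one value per line.
#' Timestamped files must be uniformly sampled (constant interval within
#' 1e-6 relative); the first offending index is reported otherwise. For the
#' value-only layouts the sampling interval `dt` must be supplied.
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"time_value"`, `"value"`, `"plain"`.
#' @param dt sampling interval in minutes (required without timestamps).
#' @param name label for the series (default: file name).
#' @return A [rhythm_ts()].
#' @seealso [write_series()], [write_serial_result()]
#' @export
read_series <- function(path, format = c("auto", "time_value", "value",
                                         "plain"), dt = NULL, name = NULL) {
  format <- match.arg(format)
  if (is.null(name)) name <- basename(path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl(",", first)) {
      if (grepl("time", tolower(first))) "time_value" else "value"
    } else "plain"
  }
  if (format == "plain") {
    if (is.null(dt)) stop("'dt' is required for value-only input")
    v <- scan(path, what = numeric(), quiet = TRUE, na.strings = c("NA", ""))
    return(rhythm_ts(v, dt = dt, name = name))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "value") {
    if (is.null(dt)) stop("'dt' is required for value-only input")
    return(rhythm_ts(as.numeric(df[[1]]), dt = dt, name = name))
  }
  tcol <- df[[1]]; vals <- as.numeric(df[[2]])
  tm <- suppressWarnings(as.numeric(tcol))
  start <- NULL
  if (any(is.na(tm))) {
    stamps <- as.POSIXct(tcol, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS",
                                        "%Y-%m-%d %H:%M"))
    if (any(is.na(stamps)))
      stop("unparseable timestamp at line ", which(is.na(stamps))[1] + 1L)
    tm <- as.numeric(difftime(stamps, stamps[1], units = "mins"))
    start <- stamps[1]
  }
  if (length(tm) > 1L) {
    d <- diff(tm)
    rel <- abs(d - d[1]) / d[1]
    if (any(rel > 1e-6))
      stop("non-uniform sampling: first gap at index ",
           which(rel > 1e-6)[1] + 1L)
    dt_file <- d[1]
    if (!is.null(dt) && abs(dt - dt_file) / dt_file > 1e-6)
      warning("declared dt ignored; file sampling interval is ", dt_file)
    dt <- dt_file
  } else if (is.null(dt)) stop("'dt' is required for a single-row file")
  rhythm_ts(vals, dt = dt, start_time = start, name = name)
}

#' Write a time series (or serial result) as CSV
#'
#' `write_series()` writes `time,value` rows (time in minutes from the
#' origin); the round trip through [read_series()] is lossless.
#' `write_serial_result()` writes the Z series with columns
#' `section_index,start_time,value,flags`.
#'
#' @param ts a [rhythm_ts()].
#' @param path output file.
#' @export
write_series <- function(ts, path) {
  stopifnot(inherits(ts, "rhythm_ts"))
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @param sr a `serial_result` from [serial_apply()].
#' @export
write_serial_result <- function(sr, path) {
  stopifnot(inherits(sr, "serial_result"))
  utils::write.csv(as.data.frame(sr), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
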