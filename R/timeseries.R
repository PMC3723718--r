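#' Uniformly sampled rhythm time series
#'
#' The basic container of the package: an ordered vector of observations
#' `x_1 .. x_N` recorded at a constant sampling interval `dt` (minutes).
#' Missing observations are carried as `NA` and their count is tracked; most
#' per-section statistics skip them, subject to a maximum missing fraction
#' (see [serial_apply()]).
#'
#' @param values numeric vector of observations (arbitrary units). `NA`
#'   marks a missing sample.
#' @param dt sampling interval in minutes (> 0).
#' @param start_time optional wall-clock origin (`POSIXct` or numeric
#'   minutes); purely descriptive.
#' @param name free-text label used in printouts and plots.
#'
#' @return An object of class `rhythm_ts`: a list with elements `values`,
#'   `dt`, `start_time`, `name` and `n_missing`.
#' @seealso [read_series()], [synth_series()], [segment()]
#' @examples
#' ts <- rhythm_ts(sin(2 * pi * (1:96) / 96), dt = 15, name = "demo")
#' n_samples(ts)
#' nyquist_frequency(ts)  # cycles per minute
#' @export
rhythm_ts <- function(values, dt, start_time = NULL, name = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a rhythm_ts needs at least one sample")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (minutes)")
  structure(
    list(values = values, dt = dt, start_time = start_time,
         name = as.character(name), n_missing = sum(is.na(values))),
    class = "rhythm_ts"
  )
}

#' @export
print.rhythm_ts <- function(x, ...) {
  cat(sprintf("<rhythm_ts>%s N=%d dt=%g min (%.2f days)%s\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              length(x$values), x$dt,
              length(x$values) * x$dt / 1440,
              if (x$n_missing > 0) sprintf(" [%d missing]", x$n_missing) else ""))
  invisible(x)
}

#' @export
as.data.frame.rhythm_ts <- function(x, ...) {
  data.frame(time = (seq_along(x$values) - 1) * x$dt, value = x$values)
}

#' Number of samples in a series
#' @param ts a [rhythm_ts()] object.
#' @return Integer sample count `N`.
#' @export
n_samples <- function(ts) {
  stopifnot(inherits(ts, "rhythm_ts"))
  length(ts$values)
}

#' Nyquist frequency of a series
#'
#' The highest analyzable frequency, `f_N = 1/(2 dt)` in cycles per minute;
#' the shortest analyzable period is `2 dt`.
#'
#' @inheritParams n_samples
#' @return Frequency in cycles per minute.
#' @export
nyquist_frequency <- function(ts) {
  stopifnot(inherits(ts, "rhythm_ts"))
  1 / (2 * ts$dt)
}

#' Convert a normalized frequency to a period (and back)
#'
#' Frequencies are expressed as a fraction of the Nyquist frequency, so that
#' `f = 1` corresponds to the shortest analyzable period of two sampling
#' intervals. With a sampling interval of 15 minutes, `f = 0.4` corresponds
#' to a period of `2 * 15 / 0.4 = 75` minutes.
#'
#' @param f normalized frequency in (0, 1], `f = 1` at the Nyquist frequency.
#' @param dt sampling interval in minutes.
#' @return `frequency_to_period()`: period in minutes.
#'   `period_to_frequency()`: normalized frequency.
#' @examples
#' frequency_to_period(0.4, dt = 15)  # 75 minutes
#' @export
frequency_to_period <- function(f, dt) {
  if (any(!is.finite(f)) || any(f <= 0)) stop("'f' must be > 0")
  if (any(f > 1)) stop("'f' must be <= 1 (f = 1 is the Nyquist frequency)")
  2 * dt / f
}

#' @rdname frequency_to_period
#' @param period period in minutes (>= 2 * dt).
#' @export
period_to_frequency <- function(period, dt) {
  if (any(!is.finite(period)) || any(period <= 0)) stop("'period' must be > 0")
  f <- 2 * dt / period
  if (any(f > 1 + 1e-12))
    stop("'period' shorter than two sampling intervals (above Nyquist)")
  pmin(f, 1)
}

# internal: coerce numeric vector or rhythm_ts to values + dt
.ts_values <- function(x, dt = NULL) {
  if (inherits(x, "rhythm_ts")) list(values = x$values, dt = x$dt)
  else list(values = as.numeric(x), dt = if (is.null(dt)) 1 else dt)
}
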