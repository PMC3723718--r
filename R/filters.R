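#' Moving-average and moving-median filters
#'
#' Simple low-pass filters for pre-analysis noise reduction. The filtered
#' value at an interior point is the mean (or median) of the symmetric window
#' of `M = 2n + 1` samples centred on it. At the series boundaries the window
#' shrinks to the available samples, so the output has the same length and
#' alignment as the input. Missing values are excluded from the window
#' statistic; a window with no present value yields `NA`. The running median
#' is recommended for count-like data because it removes isolated aberrant
#' spikes that would displace a moving average.
#'
#' @param x numeric vector or [rhythm_ts()].
#' @param n half-window: `n` samples either side of the reference point.
#' @return Filtered series of the same type and length as `x`.
#' @seealso [transfer_function()] for the analytic attenuation of the moving
#'   average.
#' @examples
#' moving_average(c(0, 0, 1, 0, 0), 1)   # impulse spread to 1/3
#' moving_median(c(5, 5, 1000, 5, 5), 2) # spike removed
#' @export
moving_average <- function(x, n) {
  v <- if (inherits(x, "rhythm_ts")) x$values else as.numeric(x)
  N <- length(v)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  if (2L * n + 1L > N) stop("window larger than series")
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  cs <- c(0, cumsum(v0))
  ck <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(N) - n, 1L)
  hi <- pmin(seq_len(N) + n, N)
  s <- cs[hi + 1L] - cs[lo]
  k <- ck[hi + 1L] - ck[lo]
  out <- ifelse(k > 0, s / k, NA_real_)
  if (inherits(x, "rhythm_ts")) rhythm_ts(out, x$dt, x$start_time, x$name) else out
}

#' @rdname moving_average
#' @export
moving_median <- function(x, n) {
  v <- if (inherits(x, "rhythm_ts")) x$values else as.numeric(x)
  N <- length(v)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  if (2L * n + 1L > N) stop("window larger than series")
  out <- vapply(seq_len(N), function(i) {
    w <- v[max(1L, i - n):min(N, i + n)]
    w <- w[!is.na(w)]
    if (length(w) == 0L) return(NA_real_)
    # lower-median convention for even counts (shrunken edge windows)
    sort(w)[ceiling(length(w) / 2)]
  }, numeric(1))
  if (inherits(x, "rhythm_ts")) rhythm_ts(out, x$dt, x$start_time, x$name) else out
}

#' Transfer function of the moving average
#'
#' Attenuation `H(f)` of a sinusoid of normalized frequency `f` by a moving
#' average of `M = 2n + 1` points: the amplitude ratio after/before
#' filtering. Frequencies are normalized as in [frequency_to_period()]
#' (`f = 1` at the Nyquist frequency, i.e. a period of two sampling
#' intervals), so a sinusoid at `f` completes one cycle every `2/f` samples
#' and
#' \deqn{H(f) = \left| \frac{\sin(\pi f M / 2)}{M \sin(\pi f / 2)} \right|}
#' `H(0) = 1` by continuity (DC passes through). Zeros occur where the
#' window spans whole cycles (`f M / 2` integer).
#'
#' @param f normalized frequency in \[0, 1\] (vectorized).
#' @param M window width, an odd integer >= 1.
#' @return Attenuation in \[0, 1\].
#' @examples
#' transfer_function(0.4, 5)  # 0: a 5-point window spans one 5-sample cycle
#' transfer_function(0.5, 3)  # 1/3
#' @export
transfer_function <- function(f, M) {
  M <- as.integer(M)
  if (is.na(M) || M < 1L || M %% 2L == 0L)
    stop("'M' must be an odd integer >= 1")
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("'f' must lie in [0, 1]")
  den <- M * sin(pi * f / 2)
  out <- ifelse(f == 0, 1, abs(sin(pi * f * M / 2)) / ifelse(den == 0, NA, den))
  pmin(out, 1)
}

#' Dichotomize a series by a threshold
#'
#' Transforms values into 0/1 by a threshold `u` resolved from the data
#' itself: `y' = 1` where `y >= u`, else 0. Used to sharpen square-ish
#' activity patterns before flank fitting ([flank_heaviside()]). For a
#' constant series with a mean/median threshold every value equals `u`, so
#' the output is all ones (documented behaviour, not an error).
#'
#' @param y numeric vector (a section).
#' @param threshold one of `"median"` (default), `"mean"`, `"percentile"`,
#'   or ignored when `u` is given.
#' @param q percentile in (0, 100), required for `threshold = "percentile"`.
#' @param u optional explicit threshold value, overriding `threshold`.
#' @return Integer vector of 0/1, same length as `y` (`NA` kept as `NA`).
#' @examples
#' dichotomize(c(1, 2, 3, 4))              # 0 0 1 1 (median 2.5)
#' dichotomize(c(1, 2, 3, 4), u = 10)      # all 0
#' @export
dichotomize <- function(y, threshold = c("median", "mean", "percentile"),
                        q = NULL, u = NULL) {
  y <- as.numeric(y)
  if (length(y) == 0L) stop("'y' must be non-empty")
  if (is.null(u)) {
    threshold <- match.arg(threshold)
    u <- switch(threshold,
      median = stats::median(y, na.rm = TRUE),
      mean = mean(y, na.rm = TRUE),
      percentile = {
        if (is.null(q) || q <= 0 || q >= 100)
          stop("'q' in (0, 100) required for percentile threshold")
        stats::quantile(y, q / 100, na.rm = TRUE, names = FALSE)
      })
  }
  as.integer(y >= u)
}
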