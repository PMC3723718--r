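#' Sinusoid-Gaussian wavelet kernel
#'
#' A sine wave of period `T` modulated by a Gaussian envelope, with a
#' support of `support_cycles` full cycles (length odd-adjusted so the
#' kernel has an exact centre). The Gaussian sigma defaults to one sixth of
#' the support, so the envelope essentially vanishes at the support edges.
#' Being an odd function under an even envelope, the kernel sums exactly to
#' zero: its convolution is insensitive to the series mean, and a linear
#' trend in the input only adds a constant offset to the output (equivalent
#' to a small threshold shift), leaving the marker spacing untouched.
#'
#' @param T period in samples (>= 4).
#' @param support_cycles support length in cycles (default 3).
#' @param sigma Gaussian sigma in samples (default `support/6`).
#' @return An object of class `wavelet_kernel`: list with `w` (kernel
#'   values), `T`, `support`, `sigma`, `half` (half-width in samples).
#' @examples
#' k <- make_wavelet(T = 24)
#' sum(k$w)  # 0 by antisymmetry
#' @export
make_wavelet <- function(T, support_cycles = 3, sigma = NULL) {
  if (!is.finite(T) || T < 4) stop("'T' must be >= 4 samples")
  support <- support_cycles * T
  half <- floor(support / 2)
  if (is.null(sigma)) sigma <- support / 6
  u <- (-half):half
  w <- sin(2 * pi * u / T) * exp(-u^2 / (2 * sigma^2))
  structure(list(w = w, T = as.numeric(T), support = 2 * half + 1,
                 sigma = sigma, half = half),
            class = "wavelet_kernel")
}

#' Wavelet convolution g(t)
#'
#' Convolves the series with a [make_wavelet()] kernel and smooths the
#' result with a short moving average (default window `T/6`, odd-adjusted)
#' to remove noise before marker extraction. The output is indexed at the
#' kernel centre, so marker positions map directly to input time; the edge
#' regions of width `support/2`, where the kernel does not fit, are `NA`.
#'
#' Because the kernel is antisymmetric (sine phase), `g` is in quadrature
#' with the rhythm: for a sinusoidal input of period `T`, the maxima of `g`
#' sit a fixed quarter-cycle after the input peaks, an offset that is
#' constant across cycles and therefore cancels in drift and group-phase
#' comparisons (see the methods vignette).
#'
#' @param ts a [rhythm_ts()] or numeric vector.
#' @param kernel a `wavelet_kernel`, or a period in samples (a default
#'   kernel is built).
#' @param smooth_window moving-average width in samples (odd-adjusted);
#'   default `T/6`; 1 disables smoothing.
#' @return An object of class `wavelet_conv`: list with `g` (same length as
#'   the input, `NA` at the edges), `T`, `edge` (unusable edge width) and
#'   `dt`.
#' @export
wavelet_convolve <- function(ts, kernel, smooth_window = NULL) {
  tv <- .ts_values(ts)
  if (!inherits(kernel, "wavelet_kernel")) kernel <- make_wavelet(kernel)
  x <- tv$values
  if (length(x) <= kernel$support) stop("series shorter than the kernel support")
  # stats::filter with the symmetric kernel indexed -half..half performs the
  # true convolution sum_k w(k) x(t - k), NA outside the valid region
  g <- as.numeric(stats::filter(x, kernel$w, method = "convolution", sides = 2))
  if (is.null(smooth_window)) smooth_window <- round(kernel$T / 6)
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= 3L) {
    valid <- !is.na(g)
    g[valid] <- moving_average(g[valid], (w - 1L) %/% 2L)
  }
  structure(list(g = g, T = kernel$T, edge = kernel$half, dt = tv$dt),
            class = "wavelet_conv")
}

#' Per-cycle phase markers from a wavelet convolution
#'
#' Scans the smoothed convolution `g(t)` for per-cycle phase markers: the
#' *onset* where `g` crosses the threshold upward, the *middle* at the local
#' maximum of `g` between consecutive onsets, and the *offset* where `g`
#' crosses the threshold downward. Upward crossings closer than `T/4` to the
#' previous accepted onset are suppressed as noise (at most one onset per
#' cycle). An empty marker set (no crossings) is returned with a flag rather
#' than an error.
#'
#' @param g a `wavelet_conv` from [wavelet_convolve()].
#' @param threshold crossing threshold on `g` (default 0).
#' @return An object of class `marker_set`: a data.frame with columns
#'   `cycle`, `onset`, `middle`, `offset` (sample indices) and
#'   `onset_time`, `middle_time`, `offset_time` (minutes), with attribute
#'   `flag = "no_crossings"` when empty.
#' @export
phase_markers <- function(g, threshold = 0) {
  stopifnot(inherits(g, "wavelet_conv"))
  v <- g$g
  T <- g$T
  n <- length(v)
  up <- which(v[-1] >= threshold & v[-n] < threshold) + 1L
  up <- up[!is.na(v[up]) & !is.na(v[pmax(up - 1L, 1L)])]
  # refractory suppression: at most one onset per cycle
  onsets <- integer(0)
  for (i in up) {
    if (length(onsets) == 0L || i - onsets[length(onsets)] >= T / 4)
      onsets <- c(onsets, i)
  }
  if (length(onsets) == 0L) {
    out <- data.frame(cycle = integer(0), onset = integer(0),
                      middle = integer(0), offset = integer(0),
                      onset_time = numeric(0), middle_time = numeric(0),
                      offset_time = numeric(0))
    attr(out, "flag") <- "no_crossings"
    class(out) <- c("marker_set", class(out))
    return(out)
  }
  ncyc <- length(onsets)
  middle <- offset <- rep(NA_integer_, ncyc)
  for (k in seq_len(ncyc)) {
    to <- if (k < ncyc) onsets[k + 1L] - 1L else min(n, onsets[k] + ceiling(T))
    seg <- v[onsets[k]:to]
    if (all(is.na(seg))) next
    middle[k] <- onsets[k] - 1L + which.max(seg)
    down <- which(seg[-1] < threshold & seg[-length(seg)] >= threshold)
    if (length(down) > 0L) offset[k] <- onsets[k] + down[1]
  }
  out <- data.frame(cycle = seq_len(ncyc), onset = onsets,
                    middle = middle, offset = offset,
                    onset_time = (onsets - 1) * g$dt,
                    middle_time = (middle - 1) * g$dt,
                    offset_time = (offset - 1) * g$dt)
  class(out) <- c("marker_set", class(out))
  out
}

#' Rayleigh test of phase homogeneity
#'
#' Tests whether a set of phase angles is concentrated rather than uniform:
#' each phase becomes a unit vector, and `r` is the length of their mean
#' vector, between 0 (uniform scatter) and 1 (identical phases). The
#' critical value at p = 0.05 is `r_crit = 1.6732268 / v^0.492018` for `v`
#' cases; `r > r_crit` rejects uniformity.
#'
#' @param angles numeric vector of phase angles in radians (v >= 2).
#' @return An object of class `rayleigh_result`: list with `r`, `v`,
#'   `r_crit`, `significant` and `mean_angle` (radians in \[0, 2 pi)).
#' @examples
#' rayleigh_r(rep(1, 10))$r           # 1
#' rayleigh_r(2 * pi * (0:9) / 10)$r  # 0 (uniform)
#' @export
rayleigh_r <- function(angles) {
  angles <- as.numeric(angles)
  angles <- angles[!is.na(angles)]
  v <- length(angles)
  if (v < 2L) stop("Rayleigh test needs at least 2 angles")
  a <- mean(cos(angles)); b <- mean(sin(angles))
  r <- sqrt(a^2 + b^2)
  r_crit <- 1.6732268 / v^0.492018
  structure(list(r = r, v = v, r_crit = r_crit,
                 significant = r > r_crit,
                 mean_angle = atan2(b, a) %% (2 * pi)),
            class = "rayleigh_result")
}

#' @export
print.rayleigh_result <- function(x, ...) {
  cat(sprintf("<rayleigh> r=%.4f (v=%d, crit=%.4f)%s mean angle %.3f rad\n",
              x$r, x$v, x$r_crit, if (x$significant) " *" else "",
              x$mean_angle))
  invisible(x)
}

#' Wavelet scalogram over a period grid
#'
#' Optional period scan: repeats [wavelet_convolve()] for a grid of kernel
#' periods and stacks the (absolute, per-row maximum) responses, giving a
#' coarse time-period picture. Marker extraction remains single-period; the
#' scan helps choose that period.
#'
#' @param ts a [rhythm_ts()] or numeric vector.
#' @param periods kernel periods in samples.
#' @param ... passed to [wavelet_convolve()].
#' @return Matrix (length(periods) x N) of smoothed convolution values.
#' @export
wavelet_scan <- function(ts, periods, ...) {
  tv <- .ts_values(ts)
  out <- matrix(NA_real_, length(periods), length(tv$values))
  for (i in seq_along(periods))
    out[i, ] <- wavelet_convolve(tv$values, make_wavelet(periods[i]), ...)$g
  rownames(out) <- as.character(periods)
  out
}
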