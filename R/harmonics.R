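#' Least-squares harmonic (Fourier) decomposition of a section
#'
#' Fits the periodic-regression model
#' \deqn{y(t) = c_0 + \sum_{i=1}^{h} c_i \cos(i \omega t - \theta_i),
#'   \qquad \omega = 2\pi/T}
#' by ordinary least squares of `y` on `1, cos(i w t), sin(i w t)`,
#' `t = 1..l`. When the section length is an integer multiple of `T` the
#' regressors are orthogonal and the estimates equal the discrete-Fourier
#' coefficients, so each harmonic is independent of the others; otherwise a
#' warning is issued and the joint (non-orthogonal) least-squares solution
#' is returned, since independent per-harmonic estimates would be biased.
#'
#' @param y numeric section values.
#' @param T fundamental period in samples (real > 0).
#' @param h number of harmonics; default `min(12, floor(T/2))`, capped at
#'   the within-cycle Nyquist limit `T/2`.
#' @return An object of class `harmonic_spectrum`: list with `mesor` (c0),
#'   `amplitude` (c_1..c_h), `phase` (theta_1..theta_h, radians in
#'   \[0, 2 pi)), `A`/`B` (cosine/sine coefficients), `T`, `h`, `orthogonal`
#'   and `fitted`.
#' @seealso [power_spectrum()], [serial_spectrum()], [dual_period_fit()]
#' @examples
#' i <- 1:24
#' y <- 3 + 2 * cos(2 * pi * i / 24 - 1)
#' fit <- harmonic_fit(y, T = 24, h = 4)
#' round(c(fit$mesor, fit$amplitude[1], fit$phase[1]), 6)  # 3 2 1
#' @export
harmonic_fit <- function(y, T, h = NULL) {
  y <- as.numeric(y)
  l <- length(y)
  if (!is.finite(T) || T <= 0) stop("'T' must be > 0")
  if (is.null(h)) h <- min(12L, floor(T / 2))
  h <- as.integer(h)
  if (h < 1L) stop("'h' must be >= 1")
  if (h > T / 2)
    stop("'h' exceeds the within-cycle Nyquist limit T/2")
  orth <- abs(l / T - round(l / T)) < 1e-8
  if (!orth)
    warning("section length is not a multiple of T: ",
            "falling back to joint (non-orthogonal) least squares")
  t <- seq_len(l)
  w <- 2 * pi / T
  X <- matrix(1, l, 1 + 2 * h)
  for (i in seq_len(h)) {
    X[, 2 * i] <- cos(i * w * t)
    X[, 2 * i + 1] <- sin(i * w * t)
  }
  # drop numerically zero columns (sine at the Nyquist harmonic T/i = 2)
  keep <- colSums(X^2) > 1e-12
  fit <- stats::lm.fit(X[, keep, drop = FALSE], y)
  beta <- numeric(ncol(X))
  beta[keep] <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  A <- beta[2 * seq_len(h)]
  B <- beta[2 * seq_len(h) + 1]
  structure(list(mesor = beta[1],
                 amplitude = sqrt(A^2 + B^2),
                 phase = atan2(B, A) %% (2 * pi),
                 A = A, B = B, T = as.numeric(T), h = h,
                 orthogonal = orth,
                 fitted = as.numeric(X %*% beta)),
            class = "harmonic_spectrum")
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  cat(sprintf("<harmonic_spectrum> T=%g, h=%d, mesor=%.4g%s\n", x$T, x$h,
              x$mesor, if (!x$orthogonal) " (non-orthogonal fit)" else ""))
  print(data.frame(harmonic = seq_len(x$h),
                   amplitude = signif(x$amplitude, 5),
                   phase = signif(x$phase, 5),
                   power = signif(power_spectrum(x), 5)))
  invisible(x)
}

#' Power spectrum of a harmonic fit
#'
#' Fraction of oscillatory power carried by each harmonic:
#' `p_i = c_i^2 / sum_j c_j^2`, summing to 1. Expressing harmonics as power
#' fractions makes sections of different overall amplitude comparable.
#'
#' @param spec a `harmonic_spectrum` from [harmonic_fit()].
#' @return Numeric vector of power fractions `p_1..p_h`; all-`NA` with a
#'   warning when every amplitude is zero.
#' @export
power_spectrum <- function(spec) {
  stopifnot(inherits(spec, "harmonic_spectrum"))
  tot <- sum(spec$amplitude^2)
  # relative zero: a constant section leaves only roundoff in the amplitudes
  if (max(spec$amplitude) < 1e-9 * max(abs(spec$mesor), .Machine$double.eps))
    tot <- 0
  if (tot == 0) {
    warning("all-zero amplitudes: power fractions undefined")
    return(rep(NA_real_, spec$h))
  }
  spec$amplitude^2 / tot
}

#' Serial harmonic spectrum ("graphic matrix")
#'
#' Computes [harmonic_fit()] on every section and assembles the power
#' fractions into a matrix with one row per section and one column per
#' harmonic, ready for [plot_matrix()]. A vertical moving average over rows
#' (`smooth_rows`, odd) can be applied to bring out slow changes of each
#' component.
#'
#' @param ts a [rhythm_ts()].
#' @param spec a [section_spec()]; `l` should be a multiple of `T`.
#' @param h number of harmonics (see [harmonic_fit()]).
#' @param smooth_rows odd vertical moving-average window over sections
#'   (default 0 = none).
#' @return An object of class `serial_spectrum`: list with `power`
#'   (n_sections x h matrix), `amplitude`, `mesor`, `section_starts`
#'   (minutes), `spec`, `h`.
#' @export
serial_spectrum <- function(ts, spec, h = NULL, smooth_rows = 0) {
  stopifnot(inherits(ts, "rhythm_ts"), inherits(spec, "section_spec"))
  if (is.null(h)) h <- min(12L, floor(spec$T / 2))
  secs <- segment(ts, spec)
  fits <- lapply(secs, function(s) harmonic_fit(s$values, T = spec$T, h = h))
  pw <- do.call(rbind, lapply(fits, power_spectrum))
  amp <- do.call(rbind, lapply(fits, `[[`, "amplitude"))
  if (smooth_rows >= 3) {
    n2 <- (as.integer(smooth_rows) - 1L) %/% 2L
    if (2L * n2 + 1L <= nrow(pw))
      pw <- apply(pw, 2, moving_average, n = n2)
  }
  structure(list(power = pw, amplitude = amp,
                 mesor = vapply(fits, `[[`, numeric(1), "mesor"),
                 section_starts = vapply(secs, `[[`, numeric(1), "start_time"),
                 spec = spec, h = as.integer(h)),
            class = "serial_spectrum")
}

#' Joint fit of two close periods
#'
#' When two rhythms with close periods coexist (e.g. an endogenous component
#' and a light-entrained one) no section length gives an integer number of
#' cycles for both, so the orthogonality condition fails and per-period fits
#' are biased. The remedy is a single linear model containing both periods,
#' `y ~ 1 + cos/sin(2 pi t / T1) + cos/sin(2 pi t / T2)`, solved jointly.
#' Sections should contain at least 2-3 full cycles of the longer period.
#'
#' Because the regressors are non-orthogonal there is no unique variance
#' decomposition; this function reports the variance of each component's
#' fitted wave over the section, their total, and the T2 share
#' `var(T2) / (var(T1) + var(T2))`.
#'
#' @param y numeric section values.
#' @param T1,T2 the two known periods in samples (distinct).
#' @return An object of class `dual_period_fit`: list with `T1`, `T2`,
#'   `amplitude` (length 2), `phase`, `var_fraction` (per component),
#'   `total_variance_fraction`, `ratio` (T2 share) and `fitted`.
#' @examples
#' t <- 1:480
#' y <- 2 * cos(2 * pi * t / 84) + 1 * cos(2 * pi * t / 102.67)
#' fit <- dual_period_fit(y, 84, 102.67)
#' round(fit$amplitude, 2)
#' @export
dual_period_fit <- function(y, T1, T2) {
  y <- as.numeric(y)
  l <- length(y)
  if (!is.finite(T1) || !is.finite(T2) || T1 <= 0 || T2 <= 0 || T1 == T2)
    stop("'T1' and 'T2' must be distinct positive periods")
  if (l < 2 * max(T1, T2))
    stop("section must span at least 2 cycles of the longer period")
  if (l < 3 * max(T1, T2))
    warning("fewer than 3 full cycles of the longer period")
  t <- seq_len(l)
  X <- cbind(1,
             cos(2 * pi * t / T1), sin(2 * pi * t / T1),
             cos(2 * pi * t / T2), sin(2 * pi * t / T2))
  if (kappa(X) > 1e5)
    stop("near-singular design: T1 and T2 too close for this section length")
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  f1 <- as.numeric(X[, 2:3] %*% beta[2:3])
  f2 <- as.numeric(X[, 4:5] %*% beta[4:5])
  vy <- stats::var(y)
  v1 <- stats::var(f1); v2 <- stats::var(f2)
  structure(list(T1 = T1, T2 = T2,
                 amplitude = c(sqrt(sum(beta[2:3]^2)), sqrt(sum(beta[4:5]^2))),
                 phase = c(atan2(beta[3], beta[2]) %% (2 * pi),
                           atan2(beta[5], beta[4]) %% (2 * pi)),
                 var_fraction = c(v1, v2) / vy,
                 total_variance_fraction = stats::var(as.numeric(X %*% beta)) / vy,
                 ratio = v2 / (v1 + v2),
                 fitted = as.numeric(X %*% beta)),
            class = "dual_period_fit")
}

#' @export
print.dual_period_fit <- function(x, ...) {
  cat(sprintf(paste0("<dual_period_fit> T1=%g T2=%g | amplitudes %.4g / %.4g | ",
                     "T2 share %.3f | model R2 %.3f\n"),
              x$T1, x$T2, x$amplitude[1], x$amplitude[2], x$ratio,
              x$total_variance_fraction))
  invisible(x)
}
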