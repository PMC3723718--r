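#' Sokolove-Bushell chi-square periodogram
#'
#' For each tested period `P` (in samples) the series is folded into an
#' array of `K = floor(N/P)` rows by `P` columns (truncating to `K*P`
#' complete cycles by default) and
#' \deqn{Q_P = \frac{K N \sum_h (\bar y_h - \bar y)^2}
#'                  {\sum_j (y_j - \bar y)^2}}
#' where the `\bar y_h` are the column means. A noise-free pattern that
#' repeats exactly with period `P` reproduces itself in the column means and
#' attains `Q_P = N`; the percent of variance explained is `Q_P * 100 / N`.
#' The statistic is highly sensitive to cycle-by-cycle repeatability of any
#' waveform, which also makes it respond at the subharmonics `2P, 3P, ...`
#' of a genuine rhythm (compare [lomb_scargle()]). Significance uses the
#' chi-square law with `df = K` cycles (the classical `df = P - 1` is
#' available via `df_rule`), Sidak-corrected across the tested grid.
#'
#' @param x numeric vector or [rhythm_ts()].
#' @param periods integer periods to test, in samples; periods with fewer
#'   than 2 complete cycles are dropped with a warning.
#' @param p family-wise significance level (default 0.05).
#' @param df_rule `"cycles"` (df = K, as printed) or `"columns"`
#'   (df = P - 1).
#' @param truncate fold only complete cycles (default); `FALSE` uses ragged
#'   columns over the full series.
#' @param dt sampling interval (minutes) when `x` is a bare vector, used
#'   only to report periods in minutes.
#' @return An object of class `periodogram` with fields `period` (samples),
#'   `period_minutes`, `statistic` (Q_P), `pct_variance`, `threshold`,
#'   `significant`, `df`, `K`, `N`, `method`, `p`.
#' @examples
#' y <- rep(c(1, 1, 0, 0), 2)
#' pg <- sokolove_bushell(y, periods = 2:4)
#' pg$statistic[pg$period == 4]      # 8 = N: 100% of variance
#' @export
sokolove_bushell <- function(x, periods, p = 0.05,
                             df_rule = c("cycles", "columns"),
                             truncate = TRUE, dt = NULL) {
  df_rule <- match.arg(df_rule)
  tv <- .ts_values(x, dt)
  y <- tv$values
  N <- length(y)
  periods <- sort(unique(as.integer(periods)))
  ok <- N %/% periods >= 2L
  if (!any(ok)) stop("no tested period has at least 2 complete cycles")
  if (!all(ok)) {
    warning(sum(!ok), " period(s) dropped: fewer than 2 complete cycles")
    periods <- periods[ok]
  }
  if (stats::var(y, na.rm = TRUE) == 0)
    stop("constant series: Q_P undefined")
  np <- length(periods)
  Q <- Nloc <- K <- numeric(np)
  for (i in seq_len(np)) {
    P <- periods[i]
    k <- N %/% P
    if (truncate) {
      yt <- y[seq_len(k * P)]
      colm <- colMeans(matrix(yt, nrow = k, byrow = TRUE), na.rm = TRUE)
      nn <- k * P
    } else {
      yt <- y
      colm <- as.numeric(tapply(yt, (seq_len(N) - 1L) %% P, mean, na.rm = TRUE))
      nn <- N
    }
    ybar <- mean(yt, na.rm = TRUE)
    Q[i] <- k * nn * sum((colm - ybar)^2) / sum((yt - ybar)^2, na.rm = TRUE)
    Nloc[i] <- nn; K[i] <- k
  }
  df <- if (df_rule == "cycles") K else periods - 1
  alpha <- sidak_per_test(p, np)
  thr <- stats::qchisq(1 - alpha, df = df)
  structure(list(period = periods,
                 period_minutes = periods * tv$dt,
                 statistic = Q,
                 pct_variance = Q * 100 / Nloc,
                 threshold = thr, significant = Q > thr,
                 df = df, K = K, N = N,
                 method = "sokolove_bushell", p = p),
            class = "periodogram")
}

# computational core of the Lomb-Scargle periodogram.
# Y: N x R matrix of series sharing `times` (sample units); returns the
# np x R statistic matrix. Standard: variance-normalized, max (N-1)/2.
# Floating: generalized (floating-mean) least-squares form, max 1.
.lsp_statistic <- function(Y, times, periods, floating) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  omega <- 2 * pi / periods
  ang <- outer(times, omega)                       # N x np
  if (floating) {
    Z <- scale(Y, center = TRUE, scale = TRUE)     # N(0, 1), sd denom N-1
    cosM <- cos(ang); sinM <- sin(ang)
    Cm <- colMeans(cosM); Sm <- colMeans(sinM)
    CC <- colMeans(cosM^2) - Cm^2
    SS <- colMeans(sinM^2) - Sm^2
    CS <- colMeans(cosM * sinM) - Cm * Sm
    YC <- crossprod(cosM, Z) / N                   # np x R (mean of z*cos)
    YS <- crossprod(sinM, Z) / N
    YY <- (N - 1) / N                              # mean of z^2
    D <- CC * SS - CS^2
    P <- (SS * YC^2 + CC * YS^2 - 2 * CS * YC * YS) / (YY * D)
  } else {
    Yc <- sweep(Y, 2, colMeans(Y))
    s2 <- colSums(Yc^2) / (N - 1)
    if (any(s2 == 0)) stop("constant series: periodogram undefined")
    tau_ang <- 0.5 * atan2(colSums(sin(2 * ang)), colSums(cos(2 * ang)))
    angt <- sweep(ang, 2, tau_ang)
    cosM <- cos(angt); sinM <- sin(angt)
    CC <- colSums(cosM^2); SS <- colSums(sinM^2)
    CY <- crossprod(cosM, Yc)                      # np x R
    SY <- crossprod(sinM, Yc)
    P <- sweep(CY^2 / CC + SY^2 / SS, 2, 2 * s2, "/")
  }
  P
}

#' Lomb-Scargle periodogram (standard and floating-mean)
#'
#' Least-squares spectral statistic testing each period of a grid
#' independently. The standard (variance-normalized) form is
#' \deqn{P(\omega) = \frac{1}{2 s^2}\left[\frac{CY^2}{CC} +
#'   \frac{SY^2}{SS}\right]}
#' with the phase origin `tau` chosen per frequency so the cosine and sine
#' sums decouple; its maximum, reached by a noise-free sinusoid, is
#' `(N-1)/2`. The generalized "floating mean" variant re-fits the mean
#' jointly with the sinusoid at every frequency (values are first normalized
#' to mean 0, sd 1), removing the long-period bias of short sections; its
#' statistic is the fraction of variance explained, with maximum 1, so
#' `100 * P` reads directly as percent variance. Unlike
#' [sokolove_bushell()], the Lomb-Scargle statistic does not respond at
#' subharmonics of a rhythm, and it accepts non-uniform sampling via
#' explicit `times`.
#'
#' @param x numeric vector or [rhythm_ts()].
#' @param periods periods to test, in samples (real values allowed), each in
#'   `(2, N]`.
#' @param times optional explicit sample times (same units as `periods`,
#'   i.e. samples); defaults to `1:N` (uniform sampling).
#' @param floating use the generalized floating-mean form?
#' @param p family-wise significance level.
#' @param multiplicity `"samples"` uses `m = N` in the threshold's Sidak
#'   exponent (as conventionally printed); `"periods"` uses the number of
#'   tested periods.
#' @param dt sampling interval (minutes) when `x` is a bare vector.
#' @return An object of class `periodogram`; `pct_variance` is the statistic
#'   rescaled by its theoretical maximum.
#' @examples
#' t <- 1:240
#' y <- sin(2 * pi * t / 24)
#' pg <- lomb_scargle(y, periods = 20:30, floating = TRUE)
#' max(pg$statistic)  # 1
#' @export
lomb_scargle <- function(x, periods, times = NULL, floating = FALSE,
                         p = 0.05, multiplicity = c("samples", "periods"),
                         dt = NULL) {
  multiplicity <- match.arg(multiplicity)
  tv <- .ts_values(x, dt)
  y <- tv$values
  keep <- !is.na(y)
  if (is.null(times)) times <- seq_along(y)
  y <- y[keep]; times <- times[keep]
  N <- length(y)
  if (N < 8L) stop("Lomb-Scargle needs at least 8 samples")
  periods <- sort(as.numeric(periods))
  span <- diff(range(times)) + 1
  if (any(periods <= 2) || any(periods > span))
    stop("tested periods must lie in (2 samples, series length]")
  stat <- as.numeric(.lsp_statistic(matrix(y), times, periods, floating))
  m <- if (multiplicity == "samples") N else length(periods)
  thr <- lsp_threshold(N, p = p, floating = floating, m = m)
  pmax_theory <- if (floating) 1 else (N - 1) / 2
  structure(list(period = periods,
                 period_minutes = periods * tv$dt,
                 statistic = stat,
                 pct_variance = 100 * stat / pmax_theory,
                 threshold = thr, significant = stat > thr,
                 N = N,
                 method = if (floating) "lomb_scargle_floating" else "lomb_scargle",
                 p = p),
            class = "periodogram")
}

#' Significance threshold for the Lomb-Scargle periodogram
#'
#' Statistic level exceeded with family-wise probability `p` under the
#' white-noise null, including a Sidak-type correction for `m` tests:
#' floating form
#' \deqn{P_p = 1 - \left[1 - (1-p)^{1/m}\right]^{2/(N-3)}}
#' and standard form `((N-2)/2)` times the same bracket. The per-test tail
#' of the floating statistic is exactly `Beta(1, (N-3)/2)`, so with `m`
#' equal to the number of independent tested frequencies the family-wise
#' rate is exact; `m = N` (the sample count, the conventional printed
#' choice) is conservative when fewer frequencies are tested.
#'
#' @param N sample count (>= 5).
#' @param p family-wise probability in (0, 1).
#' @param floating threshold for the floating-mean statistic?
#' @param m multiplicity in the Sidak exponent (default `N`).
#' @return Statistic threshold (same scale as the corresponding
#'   periodogram).
#' @examples
#' lsp_threshold(100, 0.05, floating = TRUE)  # ~0.1446
#' @export
lsp_threshold <- function(N, p = 0.05, floating = FALSE, m = N) {
  if (!is.finite(N) || N < 5) stop("'N' must be >= 5")
  .check_p(p); .check_m(m)
  bracket <- 1 - (1 - (1 - p)^(1 / m))^(2 / (N - 3))
  if (floating) bracket else (N - 2) / 2 * bracket
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("<periodogram> %s: %d periods, N=%d\n", x$method,
              length(x$period), x$N))
  pk <- peak_period(x)
  cat(sprintf("  peak: period %g samples (%g min), statistic %.4g%s\n",
              pk$period, pk$period_minutes, pk$statistic,
              if (pk$significant) " *" else ""))
  invisible(x)
}

#' @export
as.data.frame.periodogram <- function(x, ...) {
  data.frame(period = x$period, period_minutes = x$period_minutes,
             statistic = x$statistic, pct_variance = x$pct_variance,
             significant = x$significant)
}

#' Peak period of a periodogram
#'
#' The tested period at which the statistic is maximal; ties are broken
#' toward the shorter period, and the peak carries the significance flag of
#' its threshold.
#'
#' @param pgram a `periodogram`.
#' @return List with `period` (samples), `period_minutes`, `statistic`,
#'   `pct_variance` and `significant`.
#' @export
peak_period <- function(pgram) {
  stopifnot(inherits(pgram, "periodogram"))
  i <- which.max(pgram$statistic)   # grid sorted ascending: ties -> shorter
  list(period = pgram$period[i],
       period_minutes = pgram$period_minutes[i],
       statistic = pgram$statistic[i],
       pct_variance = pgram$pct_variance[i],
       significant = pgram$significant[i])
}

#' Serial periodogram with peak tracking
#'
#' One periodogram per section, stacked into a matrix (one row per section,
#' one column per tested period) for heatmap display, plus the per-section
#' peak period (the overlay line of serial-periodogram plots). Sections of
#' 8-10 cycles of the longest tested period are recommended
#' (Lomb-Scargle remains usable below 8 cycles; the hard floor is 2 cycles),
#' with a step of one cycle.
#'
#' @param ts a [rhythm_ts()].
#' @param spec a [section_spec()]; `spec$l` must cover at least 2 cycles of
#'   the longest tested period (warning under 8).
#' @param periods tested periods in samples.
#' @param method periodogram flavour.
#' @param p family-wise significance level per section.
#' @param normalize_rows rescale each row to max 1 (helps peak spotting but
#'   hides amplitude changes between sections)?
#' @param ... passed to the periodogram function.
#' @return An object of class `serial_periodogram`: list with `matrix`
#'   (statistic or normalized), `pct_variance`, `periods`, `peak`
#'   (data.frame: section, start_time, period, period_minutes, statistic,
#'   significant), `method`, `spec`.
#' @export
serial_periodogram <- function(ts, spec, periods,
                               method = c("lomb_scargle",
                                          "lomb_scargle_floating",
                                          "sokolove_bushell"),
                               p = 0.05, normalize_rows = FALSE, ...) {
  method <- match.arg(method)
  stopifnot(inherits(ts, "rhythm_ts"), inherits(spec, "section_spec"))
  maxP <- max(periods)
  if (spec$l < 2 * maxP)
    stop("section length below the hard floor of 2 cycles of the longest period")
  if (spec$l < 8 * maxP)
    warning("sections span fewer than 8 cycles of the longest tested period")
  secs <- segment(ts, spec)
  pgs <- lapply(secs, function(s) {
    switch(method,
      sokolove_bushell = sokolove_bushell(s$values, periods, p = p,
                                          dt = ts$dt, ...),
      lomb_scargle = lomb_scargle(s$values, periods, p = p, dt = ts$dt, ...),
      lomb_scargle_floating = lomb_scargle(s$values, periods, floating = TRUE,
                                           p = p, dt = ts$dt, ...))
  })
  stat <- do.call(rbind, lapply(pgs, `[[`, "statistic"))
  pct <- do.call(rbind, lapply(pgs, `[[`, "pct_variance"))
  if (normalize_rows) stat <- stat / apply(stat, 1, max)
  peaks <- lapply(pgs, peak_period)
  peak <- data.frame(
    section = seq_along(pgs),
    start_time = vapply(secs, `[[`, numeric(1), "start_time"),
    period = vapply(peaks, `[[`, numeric(1), "period"),
    period_minutes = vapply(peaks, `[[`, numeric(1), "period_minutes"),
    statistic = vapply(peaks, `[[`, numeric(1), "statistic"),
    significant = vapply(peaks, `[[`, logical(1), "significant"))
  structure(list(matrix = stat, pct_variance = pct,
                 periods = pgs[[1]]$period,
                 period_minutes = pgs[[1]]$period_minutes,
                 peak = peak, method = method, spec = spec),
            class = "serial_periodogram")
}
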