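#' Serial scalar descriptors
#'
#' Per-section descriptive statistics of the rhythm: mean, median,
#' percentile, minimum, maximum, total sum, variance, standard deviation or
#' range, computed on each section of the rule `spec` and returned as the
#' result series Z. Daily, non-overlapping sections (`s = l = T`) are the
#' usual choice; when `l` is not a multiple of `T` a warning is issued
#' because residual circadian oscillation then leaks into Z.
#'
#' @param ts a [rhythm_ts()].
#' @param spec a [section_spec()].
#' @param stat statistic name.
#' @param q percentile in (0, 100) for `stat = "percentile"`.
#' @param max_missing see [serial_apply()].
#' @return A [serial_apply()] `serial_result`.
#' @examples
#' ts <- synth_series("sinusoid", days = 5, dt = 60, period = 1440,
#'                    amplitude = 1, mesor = 2)
#' serial_scalar(ts, section_spec(24, 24), "mean")$values
#' @export
serial_scalar <- function(ts, spec,
                          stat = c("mean", "median", "min", "max", "sum",
                                   "variance", "sd", "range", "percentile"),
                          q = NULL, max_missing = 0.2) {
  stat <- match.arg(stat)
  if (!spec$l_multiple_of_T)
    warning("section length l is not a multiple of T: ",
            "false oscillations may appear in the Z series")
  fn <- switch(stat,
    mean = function(y) mean(y, na.rm = TRUE),
    median = function(y) stats::median(y, na.rm = TRUE),
    min = function(y) min(y, na.rm = TRUE),
    max = function(y) max(y, na.rm = TRUE),
    sum = function(y) sum(y, na.rm = TRUE),
    variance = function(y) stats::var(y, na.rm = TRUE),
    sd = function(y) stats::sd(y, na.rm = TRUE),
    range = function(y) diff(range(y, na.rm = TRUE)),
    percentile = {
      if (is.null(q) || q <= 0 || q >= 100)
        stop("'q' in (0, 100) required for stat = 'percentile'")
      function(y) stats::quantile(y, q / 100, na.rm = TRUE, names = FALSE)
    })
  name <- if (stat == "percentile") sprintf("p%g", q) else stat
  serial_apply(ts, spec, fn, stat_name = name, max_missing = max_missing)
}

#' Intradaily variability (IV)
#'
#' Fragmentation index of the rest-activity rhythm: the ratio of the mean
#' squared hour-to-hour difference to the overall variance,
#' \deqn{IV = \frac{N \sum_{i=2}^{N} (y_i - y_{i-1})^2}
#'                 {(N-1) \sum_{i=1}^{N} (y_i - \bar y)^2}}
#' IV approaches 0 for a smooth rhythm and 4 for a maximally alternating
#' (hour on / hour off) series. The formula assumes hourly sampling; finer
#' resolutions are first aggregated to hourly means unless
#' `aggregate = FALSE` (which computes at native resolution with a warning).
#'
#' @param x numeric vector of hourly values, or a [rhythm_ts()] at any
#'   resolution.
#' @param dt sampling interval in minutes when `x` is a bare vector
#'   (default 60).
#' @param aggregate aggregate sub-hourly data to hourly means first?
#' @return IV, a dimensionless value >= 0.
#' @examples
#' intradaily_variability(rep(c(0, 1), 12))  # 4
#' @export
intradaily_variability <- function(x, dt = 60, aggregate = TRUE) {
  tv <- .ts_values(x, dt)
  y <- tv$values; dt <- tv$dt
  if (dt != 60) {
    if (aggregate) {
      grp <- floor((seq_along(y) - 1) * dt / 60)
      y <- as.numeric(tapply(y, grp, mean, na.rm = TRUE))
    } else {
      warning("computing IV at native (non-hourly) resolution")
    }
  }
  y <- y[!is.na(y)]
  N <- length(y)
  if (N < 2L) stop("IV needs at least 2 values")
  den <- sum((y - mean(y))^2)
  if (den == 0) stop("undefined IV: zero variance")
  N * sum(diff(y)^2) / ((N - 1) * den)
}

#' Relative amplitude (RA) and the M10/L5 profile windows
#'
#' Non-parametric amplitude of the rest-activity rhythm. The section is
#' folded into an average daily profile; `M10` is the mean over the most
#' active 10 h window and `L5` the mean over the least active 5 h window,
#' both found by exhaustive search over all circular window placements
#' (windows may wrap midnight; ties go to the earliest start). Then
#' \deqn{RA = (M10 - L5) / (M10 + L5)}
#' which is 1 for a fully on/off pattern and 0 for a constant one. Sections
#' should span at least 5 cycles; fewer produce a warning.
#'
#' @param x numeric vector or [rhythm_ts()] of nonnegative values.
#' @param period cycle length in minutes (default 1440); must be an integer
#'   number of samples.
#' @param dt sampling interval in minutes when `x` is a bare vector.
#' @param profile_fun `mean` (default) or `median`, used across days when
#'   folding the profile.
#' @return List with `RA`, `M10`, `L5`, `m10_start`, `l5_start` (1-based
#'   profile bins) and the average `profile`.
#' @examples
#' y <- rep(c(rep(100, 12), rep(0, 12)), 6)  # 12 h on / 12 h off
#' relative_amplitude(y, period = 1440, dt = 60)$RA  # 1
#' @export
relative_amplitude <- function(x, period = 1440, dt = 60,
                               profile_fun = c("mean", "median")) {
  profile_fun <- match.arg(profile_fun)
  tv <- .ts_values(x, dt)
  y <- tv$values; dt <- tv$dt
  if (any(y < 0, na.rm = TRUE)) warning("RA expects nonnegative values")
  bins <- period / dt
  if (abs(bins - round(bins)) > 1e-8)
    stop("'period' must be an integer number of samples")
  bins <- as.integer(round(bins))
  cycles <- length(y) %/% bins
  if (cycles < 1L) stop("section shorter than one cycle")
  if (cycles < 5L) warning("RA sections should include 5 or more cycles")
  m <- matrix(y[seq_len(cycles * bins)], nrow = cycles, byrow = TRUE)
  profile <- if (profile_fun == "mean") colMeans(m, na.rm = TRUE)
             else apply(m, 2, stats::median, na.rm = TRUE)
  w10 <- max(1L, as.integer(round(600 / dt)))
  w5 <- max(1L, as.integer(round(300 / dt)))
  if (w10 > bins || w5 > bins) stop("profile shorter than the M10/L5 windows")
  circ_mean <- function(w) {
    ext <- c(profile, profile[seq_len(w - 1L)])
    cs <- c(0, cumsum(ext))
    (cs[seq_len(bins) + w] - cs[seq_len(bins)]) / w
  }
  m10s <- circ_mean(w10)
  l5s <- circ_mean(w5)
  i10 <- which.max(m10s)   # ties: earliest start
  i5 <- which.min(l5s)
  M10 <- m10s[i10]; L5 <- l5s[i5]
  if (M10 + L5 == 0) stop("undefined RA: all-zero profile")
  list(RA = (M10 - L5) / (M10 + L5), M10 = M10, L5 = L5,
       m10_start = i10, l5_start = i5, profile = profile)
}

#' Entrainment fraction
#'
#' Fraction of activity recorded during the first half of each lighting
#' cycle: sections with `s = l = T_light`, per-section value
#' `sum(first l/2 samples) / sum(all l samples)` in \[0, 1\]. A value near 1
#' means all activity falls in the first half-cycle; 0.5 means uniform
#' spread. All-zero sections yield `NA` with a flag.
#'
#' @param ts a [rhythm_ts()].
#' @param T_light lighting-cycle length in samples (even integer).
#' @return A `serial_result`.
#' @export
entrainment_fraction <- function(ts, T_light) {
  T_light <- as.integer(T_light)
  if (T_light < 2L) stop("'T_light' must be >= 2 samples")
  if (T_light %% 2L != 0L)
    warning("odd 'T_light': first half taken as floor(T/2) samples")
  spec <- section_spec(T_light, T_light, T_light)
  half <- T_light %/% 2L
  serial_apply(ts, spec, function(y) {
    tot <- sum(y, na.rm = TRUE)
    if (tot == 0) stop("all-zero section: entrainment fraction undefined")
    sum(y[seq_len(half)], na.rm = TRUE) / tot
  }, stat_name = "entrainment_fraction")
}
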