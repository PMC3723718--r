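#' Flank (activity onset/offset) detection by step-template regression
#'
#' Locates the rest-to-activity transition (positive flank, onset) or the
#' activity-to-rest transition (negative flank, offset) within a one-cycle
#' section by sliding a step template across the section and keeping the
#' offset with the highest Pearson correlation with the data.
#'
#' `flank_heaviside()` uses the unit step: 0 before the candidate position
#' `c`, 1 from `c` to the section end (`sign = "+"`); for `sign = "-"` the
#' complementary template (1 then 0) locates the negative flank. The
#' template is non-circular. By default the section is first dichotomized by
#' its median ([dichotomize()]), which sharpens noisy activity patterns;
#' `dichotomize_first = FALSE` fits the raw values.
#'
#' `flank_squarewave()` fits both flanks jointly with a *circular* square
#' wave `q = 1` on the circular interval `[c, d)`, 0 otherwise, so
#' activity blocks that wrap midnight are handled. Starting from the
#' Heaviside estimates, `d` is re-fitted given `c`, then `c` given `d`,
#' until the pair repeats (converged) or `max_iterations` is reached, in
#' which case the best-correlation pair seen is returned with
#' `converged = FALSE`.
#'
#' @param y numeric section values (one cycle of `n` samples, `n >= 4`).
#' @param sign `"+"` for the onset (positive flank), `"-"` for the offset.
#' @param dichotomize_first dichotomize `y` by a threshold first?
#' @param threshold,q threshold rule for [dichotomize()].
#' @param max_iterations iteration cap for the square-wave refinement.
#' @return An object of class `flank_estimate`: list with `onset` and/or
#'   `offset` (1-based sample index within the cycle: the first active /
#'   first inactive sample), `fit_r` (correlation at the optimum),
#'   `converged`, `iterations` and `n`.
#' @examples
#' y <- c(rep(0, 12), rep(1, 12))
#' flank_heaviside(y)$onset              # 13
#' y2 <- as.numeric((1:24) >= 7 & (1:24) < 19)
#' f <- flank_squarewave(y2)
#' c(f$onset, f$offset)                  # 7 19
#' @export
flank_heaviside <- function(y, sign = c("+", "-"), dichotomize_first = TRUE,
                            threshold = "median", q = NULL) {
  sign <- match.arg(sign)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4L) stop("need at least 4 values")
  y <- .maybe_dichotomize(y, dichotomize_first, threshold, q)
  # correlation of y with step templates theta_c (0 for i < c, 1 for i >= c),
  # c = 2..n, computed from tail sums
  ok <- !is.na(y)
  y0 <- ifelse(ok, y, 0)
  n_ok <- sum(ok)
  sy <- sum(y0); syy <- sum(y0^2)
  tail_y <- rev(cumsum(rev(y0)))        # sum_{i>=c} y
  tail_k <- rev(cumsum(rev(as.numeric(ok))))
  cs <- 2:n
  st <- tail_k[cs]                       # sum theta (over present samples)
  syt <- tail_y[cs]                      # sum y*theta
  num <- n_ok * syt - sy * st
  den <- sqrt(pmax(n_ok * syy - sy^2, 0) * pmax(n_ok * st - st^2, 0))
  r <- ifelse(den > 0, num / den, NA_real_)
  if (sign == "-") r <- -r               # complement template flips the sign
  best <- which.max(r)                   # ties: smallest c
  est <- list(n = n, fit_r = r[best], converged = TRUE, iterations = 1L,
              onset = NA_integer_, offset = NA_integer_)
  if (sign == "+") est$onset <- cs[best] else est$offset <- cs[best]
  structure(est, class = "flank_estimate")
}

# dichotomize unless that degenerates (e.g. a binary series whose median is
# an extreme); a genuinely constant section is an error either way
.maybe_dichotomize <- function(y, dichotomize_first, threshold, q) {
  if (stats::var(y, na.rm = TRUE) == 0)
    stop("constant section: flank correlation undefined")
  if (dichotomize_first) {
    yd <- dichotomize(y, threshold = threshold, q = q)
    if (stats::var(yd, na.rm = TRUE) > 0) y <- yd
  }
  y
}

# correlation of y with the circular square template [c, d) of n samples
.sq_cor <- function(y, n, c, d) {
  len <- (d - c) %% n
  if (len == 0L || len == n) return(NA_real_)
  idx <- ((seq_len(n) - c) %% n) < len
  suppressWarnings(stats::cor(y, as.numeric(idx), use = "complete.obs"))
}

#' @rdname flank_heaviside
#' @export
flank_squarewave <- function(y, dichotomize_first = TRUE, threshold = "median",
                             q = NULL, max_iterations = 25L) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4L) stop("need at least 4 values")
  if (max_iterations < 1L) stop("'max_iterations' must be >= 1")
  y <- .maybe_dichotomize(y, dichotomize_first, threshold, q)
  cc <- flank_heaviside(y, "+", dichotomize_first = FALSE)$onset
  dd <- flank_heaviside(y, "-", dichotomize_first = FALSE)$offset
  best_r <- -Inf; best <- c(cc, dd)
  converged <- FALSE; it <- 0L
  repeat {
    it <- it + 1L
    prev <- c(cc, dd)
    r_d <- vapply(seq_len(n), function(d) .sq_cor(y, n, cc, d), numeric(1))
    dd <- which.max(replace(r_d, is.na(r_d), -Inf))
    r_c <- vapply(seq_len(n), function(c) .sq_cor(y, n, c, dd), numeric(1))
    cc <- which.max(replace(r_c, is.na(r_c), -Inf))
    r_now <- .sq_cor(y, n, cc, dd)
    if (!is.na(r_now) && r_now > best_r) { best_r <- r_now; best <- c(cc, dd) }
    if (identical(c(cc, dd), prev)) { converged <- TRUE; break }
    if (it >= max_iterations) break
  }
  structure(list(onset = best[1], offset = best[2], fit_r = best_r,
                 converged = converged, iterations = it, n = n),
            class = "flank_estimate")
}

#' @export
print.flank_estimate <- function(x, ...) {
  cat(sprintf("<flank_estimate> onset=%s offset=%s r=%.3f%s (%d iter)\n",
              ifelse(is.na(x$onset), "-", x$onset),
              ifelse(is.na(x$offset), "-", x$offset),
              x$fit_r, if (!x$converged) " NOT CONVERGED" else "",
              x$iterations))
  invisible(x)
}

#' Threshold-crossing and extremum phase markers
#'
#' Simple per-section phase markers for smooth, low-noise waveforms. For the
#' crossing modes the section is first smoothed with a moving average whose
#' window is close to one third of the cycle (odd-adjusted), then the first
#' sample where the smoothed series crosses the threshold in the requested
#' direction is returned. Extremum and maximal-slope modes need no
#' threshold. Heavy smoothing distorts sharp waveforms, so these markers
#' suit only soft patterns.
#'
#' @param y numeric section values (one cycle).
#' @param mode marker type.
#' @param threshold,q threshold rule (see [dichotomize()]), crossing modes
#'   only.
#' @param smooth_window moving-average width in samples; default
#'   `length(y)/3`, odd-adjusted. Use 1 to skip smoothing.
#' @return 1-based sample index of the marker, or `NA` (with attribute
#'   `flag = "no_crossing"`) when the series never crosses the threshold.
#' @export
flank_threshold <- function(y, mode = c("crossing_up", "crossing_down",
                                        "min", "max",
                                        "max_increase", "max_decrease"),
                            threshold = "mean", q = NULL,
                            smooth_window = NULL) {
  mode <- match.arg(mode)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4L) stop("need at least 4 values")
  if (is.null(smooth_window)) smooth_window <- round(n / 3)
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2L == 0L) w <- w + 1L
  x <- if (w >= 3L) moving_average(y, (w - 1L) %/% 2L) else y
  if (mode %in% c("min", "max"))
    return(if (mode == "min") which.min(x) else which.max(x))
  if (mode %in% c("max_increase", "max_decrease")) {
    d <- diff(x)
    return(if (mode == "max_increase") which.max(d) + 1L else which.min(d) + 1L)
  }
  u <- if (is.numeric(threshold)) threshold
       else switch(threshold,
                   mean = mean(x, na.rm = TRUE),
                   median = stats::median(x, na.rm = TRUE),
                   percentile = stats::quantile(x, q / 100, na.rm = TRUE,
                                                names = FALSE))
  idx <- if (mode == "crossing_up")
    which(x[-1] >= u & x[-n] < u)
  else
    which(x[-1] < u & x[-n] >= u)
  if (length(idx) == 0L)
    return(structure(NA_integer_, flag = "no_crossing"))
  idx[1] + 1L
}

#' Alpha (activity-phase) duration
#'
#' The duration of the active phase, the circular difference between the
#' negative and positive flanks: `alpha = (offset - onset) mod T`.
#'
#' @param flanks a `flank_estimate` (from [flank_squarewave()]), or a
#'   numeric onset value when `offset` is given separately.
#' @param T cycle length in samples.
#' @param offset negative flank, when `flanks` is a bare onset.
#' @param dt optional sampling interval (minutes) to also report hours.
#' @return List with `samples`, `hours` (if `dt` given) and `fraction` of
#'   the cycle; `NA` when a flank is missing.
#' @examples
#' alpha_duration(20, T = 24, offset = 4)$samples  # 8
#' @export
alpha_duration <- function(flanks, T, offset = NULL, dt = NULL) {
  if (inherits(flanks, "flank_estimate")) {
    onset <- flanks$onset; offs <- flanks$offset
  } else {
    onset <- flanks; offs <- offset
  }
  if (is.null(offs) || is.na(onset) || is.na(offs))
    return(list(samples = NA_real_, hours = NA_real_, fraction = NA_real_))
  a <- (offs - onset) %% T
  list(samples = a,
       hours = if (!is.null(dt)) a * dt / 60 else NULL,
       fraction = a / T)
}
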