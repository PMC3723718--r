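#' Acrophase and centre-of-gravity phase estimators
#'
#' Angular (within-cycle) estimators of the central phase of a section of
#' `n` samples spanning one cycle, with sample `i` mapped to the angle
#' `2 pi i / n`.
#'
#' `acrophase()` is the phase of the fitted fundamental sinusoid,
#' \deqn{\phi = \mathrm{atan2}\left(\sum_i y_i \sin(2\pi i/n),\;
#'                                  \sum_i y_i \cos(2\pi i/n)\right)}
#' the instant at which the fitted cosine peaks.
#'
#' `cog_circular()` places each sample on the unit circle with mass `y_i`
#' and returns the angle of the centre of gravity `(a, b)`; its angle is
#' *identical* to the acrophase (the `sum(y)` normalizations cancel in
#' `b/a`), which is why the acrophase is a wrap-safe centrality parameter.
#'
#' `cog_linear()` is the classical mean time of events,
#' `phi = (2 pi / n) * sum(i y_i) / sum(y_i)`. It is **not** wrap-safe: a
#' waveform whose active phase wraps the section boundary pulls the linear
#' c.o.g. into the trough between its two fragments, a known artifact the
#' circular estimators avoid.
#'
#' @param y numeric section values (one cycle); nonnegative values expected
#'   for the centre-of-gravity interpretation (a warning is given
#'   otherwise).
#' @param dt optional sampling interval in minutes, used to express the
#'   result additionally in hours within the cycle.
#' @return An object of class `phase_estimate`: list with `angle` (radians
#'   in \[0, 2 pi)), `cycle_time` (the sample-index position of the phase,
#'   in \[0, n)), `hours` (wall-clock time within the cycle, where sample
#'   `i` sits at `(i-1)*dt`; only if `dt` is given), `a`, `b` (circular
#'   c.o.g. coordinates, circular estimators only), `method` and `flags`.
#' @examples
#' y <- 2 + cos(2 * pi * ((1:24) - 6) / 24)  # peak at sample 6
#' acrophase(y)$cycle_time                   # 6
#' cog_circular(y)$angle                     # same angle
#' @export
acrophase <- function(y, dt = NULL) {
  .phase_core(y, dt, method = "acrophase")
}

#' @rdname acrophase
#' @export
cog_circular <- function(y, dt = NULL) {
  .phase_core(y, dt, method = "cog_circular")
}

#' @rdname acrophase
#' @export
cog_linear <- function(y, dt = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("need at least 2 values")
  if (any(y < 0, na.rm = TRUE)) warning("negative values fed to c.o.g.")
  sy <- sum(y, na.rm = TRUE)
  if (sy == 0) stop("undefined phase: sum of values is zero")
  i <- seq_len(n)
  phi <- (2 * pi / n) * sum(i * y, na.rm = TRUE) / sy
  phi <- phi %% (2 * pi)
  .phase_estimate(phi, n, dt, a = NA_real_, b = NA_real_,
                  method = "cog_linear", flags = "")
}

.phase_core <- function(y, dt, method) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("need at least 2 values")
  if (method == "cog_circular" && any(y < 0, na.rm = TRUE))
    warning("negative values fed to c.o.g.")
  ang <- 2 * pi * seq_len(n) / n
  C <- sum(y * cos(ang), na.rm = TRUE)
  S <- sum(y * sin(ang), na.rm = TRUE)
  flags <- ""
  if (abs(C) < 1e-12 && abs(S) < 1e-12) {
    if (method == "acrophase")
      stop("undefined phase: zero fundamental component")
    flags <- "undefined_angle"
  }
  sy <- sum(y, na.rm = TRUE)
  if (method == "cog_circular" && sy == 0)
    stop("undefined phase: sum of values is zero")
  phi <- atan2(S, C) %% (2 * pi)
  ab <- if (method == "cog_circular") c(C, S) / sy else c(NA_real_, NA_real_)
  .phase_estimate(phi, n, dt, a = ab[1], b = ab[2], method = method,
                  flags = flags)
}

.phase_estimate <- function(angle, n, dt, a, b, method, flags) {
  ct <- angle / (2 * pi) * n
  # wall-clock hours within the cycle: sample i sits at time (i-1)*dt
  structure(list(angle = angle,
                 cycle_time = ct,
                 hours = if (!is.null(dt)) ((ct - 1) %% n) * dt / 60 else NULL,
                 a = a, b = b, n = n, method = method, flags = flags),
            class = "phase_estimate")
}

#' @export
print.phase_estimate <- function(x, ...) {
  cat(sprintf("<phase_estimate> %s: angle=%.4f rad, cycle_time=%.3f samples%s%s\n",
              x$method, x$angle, x$cycle_time,
              if (!is.null(x$hours)) sprintf(" (%.2f h)", x$hours) else "",
              if (nzchar(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' Serial phase analysis
#'
#' Applies a phase estimator ([acrophase()], [cog_circular()],
#' [cog_linear()], or a flank method via [flank_heaviside()] /
#' [flank_squarewave()]) to every section and, by default, passes the
#' resulting track through [track_phase()] so that no step between sections
#' exceeds half a cycle. Values are reported in hours within the cycle.
#'
#' @param ts a [rhythm_ts()].
#' @param spec a [section_spec()]; non-overlapping daily sections
#'   (`s = l = T`) are the usual choice for phases.
#' @param method phase estimator to use.
#' @param dichotomize_first dichotomize each section by its median before
#'   flank fitting (flank methods only; default TRUE).
#' @param track unwrap the resulting phase track with [track_phase()]?
#' @param k extrapolation depth for [track_phase()].
#' @param ... passed to the estimator.
#' @return A `serial_result` of phases in hours.
#' @export
serial_phase <- function(ts, spec,
                         method = c("acrophase", "cog_circular", "cog_linear",
                                    "onset", "offset"),
                         dichotomize_first = TRUE, track = TRUE, k = 4, ...) {
  method <- match.arg(method)
  T_h <- spec$T * ts$dt / 60
  fn <- switch(method,
    acrophase = function(y) acrophase(y, dt = ts$dt)$hours,
    cog_circular = function(y) cog_circular(y, dt = ts$dt)$hours,
    cog_linear = function(y) cog_linear(y, dt = ts$dt)$hours,
    onset = function(y)
      (flank_heaviside(y, sign = "+",
                       dichotomize_first = dichotomize_first, ...)$onset - 1) *
        ts$dt / 60,
    offset = function(y)
      (flank_heaviside(y, sign = "-",
                       dichotomize_first = dichotomize_first, ...)$offset - 1) *
        ts$dt / 60)
  out <- serial_apply(ts, spec, fn, stat_name = paste0("phase_", method))
  if (track) out$values <- track_phase(out$values, T = T_h, k = k)
  out
}
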