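#' Synthetic rhythm generator
#'
#' Seeded generator of the example series used throughout the package's
#' tests and documentation: pure and phase/period-programmed sinusoids,
#' square-wave activity patterns, two-component series with close periods,
#' waveform morphs (square to sinusoid; ultradian to circadian), count-like
#' Poisson series, and white and pink (1/f) noise. The seed fully determines
#' the output; the caller's RNG state is restored on exit.
#'
#' Noise level is expressed as a signal-to-noise ratio
#' `snr = rhythm amplitude / noise standard deviation`; `snr = Inf`
#' (default) means noise-free.
#'
#' @param kind series type.
#' @param days record length in days.
#' @param dt sampling interval in minutes.
#' @param period fundamental period in minutes (default 1440); for
#'   `two_component` supply `periods` (length 2).
#' @param amplitude rhythm amplitude (for `two_component` supply
#'   `amplitudes`, length 2; for the noise kinds this is the noise sd).
#' @param mesor constant level added to the rhythm.
#' @param peak time (minutes) of the first sinusoid peak.
#' @param onset activity onset (minutes within the cycle) for square
#'   patterns.
#' @param duty active fraction of the cycle for square patterns.
#' @param periods,amplitudes the two components of `two_component`.
#' @param shifts data.frame with columns `time` and `shift` (minutes):
#'   cumulative phase delays applied from `time` onward
#'   (`phase_program`).
#' @param period_schedule data.frame with columns `time` and `period`
#'   (minutes): piecewise instantaneous period, phase-continuous
#'   (`period_program`).
#' @param snr signal-to-noise ratio (amplitude / gaussian noise sd).
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @param name label for the resulting series.
#' @return A [rhythm_ts()].
#' @examples
#' ts <- synth_series("sinusoid", days = 2, dt = 60, period = 1440,
#'                    amplitude = 1, mesor = 2, snr = 5, seed = 1)
#' @export
synth_series <- function(kind = c("sinusoid", "square", "two_component",
                                  "phase_program", "period_program",
                                  "shape_morph", "ultradian_morph",
                                  "pink_noise", "white_noise",
                                  "poisson_counts"),
                         days = 10, dt = 15, period = 1440,
                         amplitude = 1, mesor = 0, peak = 0,
                         onset = 0, duty = 0.5,
                         periods = c(1260, 1540), amplitudes = c(1, 1),
                         shifts = NULL, period_schedule = NULL,
                         snr = Inf, seed = NULL, name = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }
  N <- round(days * 1440 / dt)
  tmin <- (seq_len(N) - 1) * dt           # minutes from origin
  total <- N * dt
  sq_wave <- function(t, T, on, du)        # +/-1 square wave
    ifelse(((t - on) %% T) < du * T, 1, -1)
  x <- switch(kind,
    sinusoid = mesor + amplitude * cos(2 * pi * (tmin - peak) / period),
    square = mesor + amplitude *
      as.numeric(((tmin - onset) %% period) < duty * period),
    two_component = {
      stopifnot(length(periods) == 2, length(amplitudes) == 2)
      mesor + amplitudes[1] * cos(2 * pi * tmin / periods[1]) +
        amplitudes[2] * cos(2 * pi * tmin / periods[2])
    },
    phase_program = {
      if (is.null(shifts)) shifts <- data.frame(time = numeric(0),
                                                shift = numeric(0))
      if (any(shifts$time < 0 | shifts$time > total))
        stop("phase-program shift beyond the series")
      off <- vapply(tmin, function(t) sum(shifts$shift[shifts$time <= t]),
                    numeric(1))
      mesor + amplitude * cos(2 * pi * (tmin - peak - off) / period)
    },
    period_program = {
      if (is.null(period_schedule))
        period_schedule <- data.frame(time = 0, period = period)
      if (any(period_schedule$time < 0 | period_schedule$time > total))
        stop("period schedule beyond the series")
      sched <- period_schedule[order(period_schedule$time), ]
      Tt <- sched$period[findInterval(tmin, sched$time, rightmost.closed = FALSE)]
      Tt[is.na(Tt)] <- sched$period[1]
      phase <- 2 * pi * cumsum(dt / Tt)
      mesor + amplitude * cos(phase)
    },
    shape_morph = {
      lambda <- seq(0, 1, length.out = N)
      sq <- sq_wave(tmin, period, onset, duty)
      sn <- cos(2 * pi * (tmin - onset - duty * period / 2) / period)
      mesor + amplitude * ((1 - lambda) * sq + lambda * sn)
    },
    ultradian_morph = {
      lambda <- seq(0, 1, length.out = N)
      mesor + amplitude * ((1 - lambda) * cos(2 * pi * tmin / (period / 8)) +
                             lambda * cos(2 * pi * tmin / period))
    },
    white_noise = mesor + stats::rnorm(N, sd = amplitude),
    pink_noise = mesor + amplitude * .pink_noise(N),
    poisson_counts = {
      lam <- pmax(mesor + amplitude * cos(2 * pi * (tmin - peak) / period), 0)
      as.numeric(stats::rpois(N, lam))
    })
  if (is.finite(snr) && !(kind %in% c("white_noise", "pink_noise"))) {
    amp0 <- if (kind == "two_component") amplitudes[1] else amplitude
    x <- x + stats::rnorm(N, sd = amp0 / snr)
  }
  rhythm_ts(x, dt = dt, name = if (is.null(name)) kind else name)
}

# 1/f ("pink") noise via spectral shaping: white gaussian spectrum scaled by
# 1/sqrt(f), inverse transformed, standardized to unit sd
.pink_noise <- function(N) {
  z <- stats::rnorm(N)
  Z <- stats::fft(z)
  f <- c(1, seq_len(N - 1))                 # DC bin left unscaled at index 1
  f <- pmin(f, N - f + 1)                   # fold to two-sided frequencies
  Z <- Z / sqrt(f)
  Z[1] <- 0
  x <- Re(stats::fft(Z, inverse = TRUE)) / N
  as.numeric(scale(x))
}
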