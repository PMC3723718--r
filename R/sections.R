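#' Section rule for serial analysis
#'
#' A serial analysis cuts the series into successive sections of `length_l`
#' samples, displaced by `step_s` samples, each analyzed in the circadian
#' range with period `period_T`. Overlapping sections (`s < l`) share data,
#' which matters both for smoothing and for multiplicity correction; see
#' [effective_multiplicity()]. For most statistics the section length should
#' be an integer multiple of `T`, otherwise a residual of the circadian
#' oscillation leaks into the result series; a flag records this condition.
#'
#' @param length_l section length in samples (integer >= 1).
#' @param step_s displacement between successive sections in samples
#'   (integer >= 1).
#' @param period_T analysis period in samples (real > 0); defaults to
#'   `length_l` (one section = one cycle).
#' @return An object of class `section_spec` with fields `l`, `s`, `T` and
#'   the logical flag `l_multiple_of_T`.
#' @examples
#' section_spec(length_l = 10, step_s = 4, period_T = 10)
#' @export
section_spec <- function(length_l, step_s, period_T = length_l) {
  l <- as.integer(length_l); s <- as.integer(step_s)
  if (is.na(l) || l < 1L) stop("'length_l' must be an integer >= 1")
  if (is.na(s) || s < 1L) stop("'step_s' must be an integer >= 1")
  if (!is.finite(period_T) || period_T <= 0) stop("'period_T' must be > 0")
  mult <- abs(l / period_T - round(l / period_T)) < 1e-8
  structure(list(l = l, s = s, T = as.numeric(period_T),
                 l_multiple_of_T = mult),
            class = "section_spec")
}

#' @export
print.section_spec <- function(x, ...) {
  cat(sprintf("<section_spec> l=%d s=%d T=%g%s\n", x$l, x$s, x$T,
              if (!x$l_multiple_of_T) " (warning: l not a multiple of T)" else ""))
  invisible(x)
}

#' Number of sections produced by a rule
#'
#' `n = floor((N - l) / s) + 1` complete sections fit in a series of `N`
#' samples.
#'
#' @param ts a [rhythm_ts()] (or integer sample count `N`).
#' @param spec a [section_spec()].
#' @return Integer section count.
#' @export
n_sections <- function(ts, spec) {
  N <- if (inherits(ts, "rhythm_ts")) length(ts$values) else as.integer(ts)
  stopifnot(inherits(spec, "section_spec"))
  if (spec$l > N) stop("series shorter than section (l > N)")
  (N - spec$l) %/% spec$s + 1L
}

#' Segment a series into sections
#'
#' Section `j` covers samples `(j-1)*s + 1 ... (j-1)*s + l` (1-based); no
#' section extends past the series end.
#'
#' @param ts a [rhythm_ts()].
#' @param spec a [section_spec()].
#' @return A list of sections, each a list with `index` (1-based section
#'   number `j`), `start_offset` (samples before the section start, i.e.
#'   `(j-1)*s`), `start_time` (minutes), and `values` (the `l` samples).
#' @examples
#' ts <- rhythm_ts(1:20, dt = 60)
#' sec <- segment(ts, section_spec(10, 4))
#' length(sec)           # 3 sections
#' sec[[2]]$values[1]    # x_5
#' @export
segment <- function(ts, spec) {
  stopifnot(inherits(ts, "rhythm_ts"), inherits(spec, "section_spec"))
  N <- length(ts$values)
  n <- n_sections(N, spec)
  lapply(seq_len(n), function(j) {
    off <- (j - 1L) * spec$s
    structure(list(index = j, start_offset = off,
                   start_time = off * ts$dt,
                   values = ts$values[(off + 1L):(off + spec$l)]),
              class = "section_view")
  })
}

#' Per-test significance level under multiplicity
#'
#' When `m` tests share data (overlapping sections, or the many periods of a
#' periodogram), the per-test level that keeps the family-wise level at `p`
#' is given by Sidak's formula `p_m = 1 - (1 - p)^(1/m)`; the Bonferroni
#' correction `p/m` is its conservative approximation, already close for
#' `m > 3`.
#'
#' @param p family-wise probability level in (0, 1).
#' @param m multiplicity (number of tests sharing data), integer >= 1.
#' @return Per-test probability level.
#' @examples
#' sidak_per_test(0.05, 4)       # 0.012741
#' bonferroni_per_test(0.05, 4)  # 0.0125
#' @export
sidak_per_test <- function(p, m) {
  .check_p(p); .check_m(m)
  1 - (1 - p)^(1 / m)
}

#' @rdname sidak_per_test
#' @export
bonferroni_per_test <- function(p, m) {
  .check_p(p); .check_m(m)
  p / m
}

.check_p <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie in (0, 1)")
}
.check_m <- function(m) {
  if (any(!is.finite(m)) || any(m < 1))
    stop("'m' must be >= 1")
}

#' Effective multiplicity of overlapping sections
#'
#' The number of section-level tests that share any one sample: with step
#' `s < l` a fixed interior sample falls inside `ceil(l/s)` windows; with
#' non-overlapping sections there is no sharing and no correction is needed.
#'
#' @param spec a [section_spec()].
#' @return Integer multiplicity `m` for use in [sidak_per_test()].
#' @export
effective_multiplicity <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  if (spec$s >= spec$l) 1L else as.integer(ceiling(spec$l / spec$s))
}

#' Apply a statistic to every section
#'
#' The generic serial driver: computes `z_j = statistic(Y_j)` for each
#' section in order, producing the result series Z. Sections whose missing
#' fraction exceeds `max_missing` yield `NA` with flag `"too_missing"`;
#' errors raised by the statistic are converted to `NA` flagged with the
#' section index and message.
#'
#' @param ts a [rhythm_ts()].
#' @param spec a [section_spec()].
#' @param statistic function taking the numeric section values (possibly
#'   containing `NA`) and returning a single number.
#' @param ... passed on to `statistic`.
#' @param stat_name label stored in the result.
#' @param max_missing maximum tolerated fraction of missing samples per
#'   section (default 0.2).
#' @return An object of class `serial_result`: list with `values` (the Z
#'   series), `section_starts` (minutes), `n_sections`, `stat_name`, `spec`,
#'   `flags` (character per section, `""` when clean) and
#'   `missing_fraction`.
#' @examples
#' ts <- rhythm_ts(rep(5, 48), dt = 60)
#' z <- serial_apply(ts, section_spec(24, 24), mean, stat_name = "mean")
#' z$values  # 5 5
#' @export
serial_apply <- function(ts, spec, statistic, ..., stat_name = "stat",
                         max_missing = 0.2) {
  stopifnot(inherits(ts, "rhythm_ts"), inherits(spec, "section_spec"),
            is.function(statistic))
  secs <- segment(ts, spec)
  n <- length(secs)
  values <- rep(NA_real_, n)
  flags <- character(n)
  missfrac <- numeric(n)
  for (j in seq_len(n)) {
    y <- secs[[j]]$values
    missfrac[j] <- mean(is.na(y))
    if (missfrac[j] > max_missing) {
      flags[j] <- "too_missing"
      next
    }
    res <- tryCatch(statistic(y, ...), error = function(e) e)
    if (inherits(res, "error")) {
      flags[j] <- sprintf("section %d: %s", j, conditionMessage(res))
    } else {
      v <- as.numeric(res)[1]
      values[j] <- v
    }
  }
  structure(list(values = values,
                 section_starts = vapply(secs, `[[`, numeric(1), "start_time"),
                 n_sections = n, stat_name = stat_name, spec = spec,
                 flags = flags, missing_fraction = missfrac),
            class = "serial_result")
}

#' @export
print.serial_result <- function(x, ...) {
  cat(sprintf("<serial_result> '%s': %d sections (l=%d s=%d T=%g)\n",
              x$stat_name, x$n_sections, x$spec$l, x$spec$s, x$spec$T))
  print(utils::head(as.data.frame(x), 6))
  if (x$n_sections > 6) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.serial_result <- function(x, ...) {
  data.frame(section_index = seq_len(x$n_sections),
             start_time = x$section_starts,
             value = x$values,
             flags = x$flags,
             stringsAsFactors = FALSE)
}

#' Monitor and unwrap a serial phase track
#'
#' Phases live on a circle of circumference `T`, so a raw serial estimate can
#' jump by nearly a full cycle when the true change is small: an apparent
#' shift of 18 h within a 24 h cycle is really a change of -6 h. Each new
#' value is therefore shifted by the integer multiple of `T` that brings it
#' within `T/2` of the value *expected* for that section. The expectation is
#' extrapolated by least-squares linear regression over the preceding
#' `min(k, available)` corrected values (with fewer than 2 predecessors the
#' previous corrected value is used); the first value passes through
#' unchanged.
#'
#' @param raw_phases numeric vector of phase values (any consistent unit,
#'   e.g. hours within the cycle).
#' @param T cycle length in the same unit.
#' @param k number of preceding sections used for the extrapolation
#'   (default 4; the useful range is 2-6).
#' @return Numeric vector of corrected (unwrapped) phases.
#' @examples
#' track_phase(c(4, 6, 8, 10), T = 24)      # unchanged: on-trend
#' track_phase(c(4, 4, 4, 22), T = 24)      # 22 is really 4 - 6 = -2
#' @export
track_phase <- function(raw_phases, T, k = 4) {
  raw <- as.numeric(raw_phases)
  if (length(raw) == 0L) stop("'raw_phases' must contain at least one value")
  if (!is.finite(T) || T <= 0) stop("'T' must be > 0")
  if (k < 1) stop("'k' must be >= 1")
  out <- raw
  for (j in seq_along(raw)[-1]) {
    prev <- out[seq_len(j - 1L)]
    prev <- prev[!is.na(prev)]
    if (is.na(raw[j])) next
    if (length(prev) == 0L) next
    use <- utils::tail(prev, min(k, length(prev)))
    expected <- if (length(use) >= 2L) {
      tt <- seq_along(use)
      fit <- stats::lm.fit(cbind(1, tt), use)
      sum(fit$coefficients * c(1, length(use) + 1L))
    } else {
      use[length(use)]
    }
    dev <- raw[j] - expected
    dev <- dev - T * floor(dev / T + 0.5)   # wrap into [-T/2, T/2)
    out[j] <- expected + dev
  }
  out
}
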