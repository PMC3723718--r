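test_that("acrophase locates the peak of a sampled cosine", {
  n <- 24
  for (i0 in c(1, 6, 12, 18, 23)) {
    y <- 2 + cos(2 * pi * ((1:n) - i0) / n)
    expect_equal(acrophase(y)$angle, 2 * pi * i0 / n, tolerance = 1e-12)
  }
  # one-point mass at i
  for (i in c(3, 17)) {
    y <- rep(0, n); y[i] <- 5
    expect_equal(acrophase(y)$angle, 2 * pi * i / n)
    expect_equal(cog_linear(y)$angle, 2 * pi * i / n)
  }
  expect_error(acrophase(rep(1, 24)), "undefined phase")
  # hours reported on the wall clock: peak sample 6 sits at 5 h (dt = 60)
  expect_equal(acrophase(2 + cos(2 * pi * ((1:24) - 6) / 24), dt = 60)$hours, 5)
})

test_that("acrophase equals the circular centre of gravity (100 seeded cases)", {
  set.seed(123)
  for (r in 1:100) {
    y <- runif(24)
    expect_angle_equal(acrophase(y)$angle, cog_circular(y)$angle, tol = 1e-9)
  }
})

test_that("circular c.o.g.: rotation equivariance, uniform degeneracy", {
  set.seed(9)
  y <- runif(24)
  phi0 <- cog_circular(y)$angle
  for (r in c(1, 5, 11)) {
    yr <- c(y[(r + 1):24], y[1:r])    # y rotated left by r samples
    expect_angle_equal(cog_circular(yr)$angle,
                       (phi0 - 2 * pi * r / 24) %% (2 * pi), tol = 1e-9)
  }
  u <- cog_circular(rep(1, 24))
  expect_equal(c(u$a, u$b), c(0, 0), tolerance = 1e-12)
  expect_equal(u$flags, "undefined_angle")
  expect_warning(cog_circular(c(-1, rep(1, 23))), "negative")
})

test_that("linear c.o.g. fails on waveforms wrapping the section boundary", {
  n <- 24
  # symmetric hump centred at n/2
  hump <- exp(-((1:n) - 12)^2 / 8)
  expect_equal(cog_linear(hump)$angle, pi, tolerance = 1e-6)
  # 12 h square block wrapping midnight: true centre at sample 2
  y <- as.numeric(((1:n) >= 20) | ((1:n) <= 7))
  circ <- cog_circular(y)$angle
  lin <- cog_linear(y)$angle
  true_centre <- 2 * pi * 1.5 / n    # block 20..24,1..7 centred at 1.5
  d_circ <- min(abs(circ - true_centre), 2 * pi - abs(circ - true_centre))
  d_lin <- min(abs(lin - true_centre), 2 * pi - abs(lin - true_centre))
  expect_lt(d_circ, 0.2)
  expect_gt(d_lin, pi / 2)           # linear estimate lands in the trough
})

test_that("Heaviside flank detection is exact on clean steps", {
  y <- c(rep(0, 12), rep(1, 12))
  f <- flank_heaviside(y, "+")
  expect_equal(f$onset, 13L)
  expect_equal(f$fit_r, 1)
  f2 <- flank_heaviside(rev(y), "-")
  expect_equal(f2$offset, 13L)
  expect_error(flank_heaviside(rep(1, 24)), "constant")
})

test_that("square-wave flank fit recovers all clean onset/offset pairs", {
  n <- 24
  for (on in c(1, 5, 7, 13, 20)) {
    for (len in c(6, 12, 16)) {
      off <- ((on - 1 + len) %% n) + 1
      y <- as.numeric((((1:n) - on) %% n) < len)
      f <- flank_squarewave(y)
      expect_equal(c(f$onset, f$offset), c(on, off),
                   info = sprintf("on=%d len=%d", on, len))
      expect_true(f$converged)
      expect_equal(f$fit_r, 1, tolerance = 1e-12)
      # exhaustive template search agrees
      o <- exhaustive_squarewave(y)
      expect_equal(c(o$c, o$d), c(on, off))
    }
  }
})

test_that("flank recovery under noise (Monte Carlo, SNR 5)", {
  set.seed(2024)
  n <- 24; on_true <- 9; off_true <- 21
  hits_h <- hits_c <- hits_d <- 0L
  for (r in 1:200) {
    y <- as.numeric((((1:n) - on_true) %% n) < 12) + rnorm(n, sd = 0.2)
    fh <- flank_heaviside(y, "+")
    if (abs(fh$onset - on_true) <= 2) hits_h <- hits_h + 1L
    fs <- flank_squarewave(y)
    dc <- min(abs(fs$onset - on_true), n - abs(fs$onset - on_true))
    dd <- min(abs(fs$offset - off_true), n - abs(fs$offset - off_true))
    if (dc <= 2) hits_c <- hits_c + 1L
    if (dd <= 2) hits_d <- hits_d + 1L
  }
  expect_gte(hits_h / 200, 0.95)
  expect_gte(hits_c / 200, 0.90)
  expect_gte(hits_d / 200, 0.90)
})

test_that("threshold-crossing and extremum markers", {
  # two cycles of period 48 with the ideal upward mean-crossing at i = 24.5
  n <- 96; P <- 48
  y <- 5 + 3 * sin(2 * pi * ((1:n) - 24) / P)
  w <- 17                               # ~ a third of the cycle, odd
  i_up <- flank_threshold(y, "crossing_up", threshold = "mean",
                          smooth_window = w)
  expect_lte(abs(i_up - 24.5), 1)
  i_down <- flank_threshold(y, "crossing_down", threshold = "mean",
                            smooth_window = w)
  expect_lte(abs(i_down - 48.5), 1)
  # peak of a clean sinusoid
  expect_equal(flank_threshold(y, "max", smooth_window = 1), which.max(y))
  # series never exceeding the threshold is flagged
  res <- flank_threshold(rep(c(0, 0.1), 12), "crossing_up", threshold = 5)
  expect_true(is.na(res))
  expect_equal(attr(res, "flag"), "no_crossing")
  # steepest rise of the sinusoid is at its upward zero crossing
  i_inc <- flank_threshold(y, "max_increase", smooth_window = 1)
  expect_lte(abs(i_inc - 24.5), 1.5)
})

test_that("alpha duration is the circular onset-offset difference", {
  expect_equal(alpha_duration(20, T = 24, offset = 4)$samples, 8)
  expect_equal(alpha_duration(7, T = 24, offset = 7)$samples, 0)
  expect_equal(alpha_duration(20, T = 24, offset = 4, dt = 60)$hours, 8)
  # clean 12 h square wave: alpha = 12 h = 50% of T
  y <- as.numeric((((1:24) - 7) %% 24) < 12)
  f <- flank_squarewave(y)
  a <- alpha_duration(f, T = 24, dt = 60)
  expect_equal(a$samples, 12)
  expect_equal(a$fraction, 0.5)
  expect_true(is.na(alpha_duration(NA, T = 24, offset = 3)$samples))
})

test_that("serial phase tracking keeps steps below half a cycle", {
  # sinusoid with a single -6 h step mid-series
  ts <- synth_series("phase_program", days = 20, dt = 60, period = 1440,
                     amplitude = 1, mesor = 2,
                     shifts = data.frame(time = 10 * 1440, shift = -360))
  z <- serial_phase(ts, section_spec(24, 24, 24), "acrophase")
  d <- diff(z$values)
  expect_true(all(abs(d) <= 12 + 1e-9))
  # one step of about -6 h, flat elsewhere
  expect_equal(sum(abs(d) > 3), 1L)
  expect_equal(d[which.max(abs(d))], -6, tolerance = 0.5)
  # all phase methods run serially
  for (m in c("cog_circular", "onset", "offset")) {
    zz <- serial_phase(ts, section_spec(24, 24, 24), m)
    expect_equal(zz$n_sections, 20L)
  }
})
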