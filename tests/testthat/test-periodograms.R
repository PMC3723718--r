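test_that("Sokolove-Bushell reproduces the hand-computed square-wave case", {
  y <- rep(c(1, 1, 0, 0), 2)
  pg <- sokolove_bushell(y, periods = 2:4)
  expect_equal(pg$statistic[pg$period == 4], 8)       # Q_P = N
  expect_equal(pg$pct_variance[pg$period == 4], 100)
  expect_equal(pg$df[pg$period == 4], 2)              # df = K cycles
  expect_error(sokolove_bushell(rep(1, 20), 2:5), "constant")
  expect_error(sokolove_bushell(y, 8), "2 complete cycles")
})

test_that("SBP reaches 100% variance for any noise-free periodic pattern", {
  set.seed(31)
  for (P in c(5, 12, 24)) {
    pattern <- runif(P)
    y <- rep(pattern, 6)
    pg <- sokolove_bushell(y, periods = 2:(3 * P))
    expect_equal(pg$pct_variance[pg$period == P], 100, tolerance = 1e-9)
    expect_true(pg$significant[pg$period == P])
  }
})

test_that("SBP responds at subharmonics, Lomb-Scargle does not", {
  P <- 50; N <- 500
  t <- 1:N
  y <- as.numeric((t %% P) < P / 2)        # square wave, period 50
  periods <- seq(25, 250, by = 1)
  sbp <- sokolove_bushell(y, periods)
  at <- function(pg, p0) pg$statistic[which.min(abs(pg$period - p0))]
  pct_at <- function(pg, p0) pg$pct_variance[which.min(abs(pg$period - p0))]
  expect_equal(pct_at(sbp, 100), 100, tolerance = 1e-9)   # 2P
  expect_equal(pct_at(sbp, 150), 100, tolerance = 1e-9)   # 3P
  expect_gte(pct_at(sbp, 100), median(sbp$pct_variance))
  lsp <- lomb_scargle(y, periods, floating = TRUE)
  expect_gt(at(lsp, 50), lsp$threshold)                    # true period found
  expect_lt(at(lsp, 100), lsp$threshold)                   # subharmonics absent
  expect_lt(at(lsp, 150), lsp$threshold)
})

test_that("LSP maxima equal their theoretical bounds on a noise-free sinusoid", {
  t <- 1:960
  y <- 2 + sin(2 * pi * t / 96)
  periods <- seq(80, 110, by = 0.5)
  std <- lomb_scargle(y, periods)
  expect_equal(max(std$statistic), (960 - 1) / 2, tolerance = 1e-6)
  flo <- lomb_scargle(y, periods, floating = TRUE)
  expect_equal(max(flo$statistic), 1, tolerance = 1e-6)
  expect_equal(flo$period[which.max(flo$statistic)], 96)
  # standard LSP invariant to adding a constant; floating to affine maps
  y2 <- y + 100
  expect_equal(lomb_scargle(y2, periods)$statistic, std$statistic,
               tolerance = 1e-9)
  y3 <- 3 * y - 7
  expect_equal(lomb_scargle(y3, periods, floating = TRUE)$statistic,
               flo$statistic, tolerance = 1e-9)
  expect_error(lomb_scargle(y, periods = c(1.5, 96)), "periods")
  expect_error(lomb_scargle(rep(2, 100), periods = 20:30), "constant")
})

test_that("LSP accepts non-uniform sampling", {
  set.seed(8)
  tt <- sort(sample(1:2000, 300))
  y <- sin(2 * pi * tt / 96) + rnorm(300, sd = 0.1)
  pg <- lomb_scargle(y, periods = seq(48, 192, 1), times = tt,
                     floating = TRUE)
  expect_equal(peak_period(pg)$period, 96, tolerance = 0.02)
  expect_true(peak_period(pg)$significant)
})

test_that("LSP threshold: closed form, monotonicity", {
  expect_equal(lsp_threshold(100, 0.05, floating = TRUE), 0.14461,
               tolerance = 1e-4)
  ps <- c(0.001, 0.01, 0.05, 0.2, 0.5)
  thr <- vapply(ps, function(p) lsp_threshold(200, p, floating = TRUE),
                numeric(1))
  expect_true(all(diff(thr) < 0))      # less stringent p, lower bar
  thr_std <- vapply(ps, function(p) lsp_threshold(200, p), numeric(1))
  expect_true(all(diff(thr_std) < 0))
  expect_error(lsp_threshold(4, 0.05), "N")
})

test_that("peak_period: argmax, tie toward shorter period, significance", {
  pg <- structure(list(period = c(20, 24, 30), period_minutes = c(20, 24, 30),
                       statistic = c(1, 5, 2), pct_variance = c(10, 50, 20),
                       threshold = 3, significant = c(FALSE, TRUE, FALSE),
                       N = 100, method = "lomb_scargle", p = 0.05),
                  class = "periodogram")
  expect_equal(peak_period(pg)$period, 24)
  pg$statistic <- c(2, 2, 2); pg$significant <- rep(FALSE, 3)
  pk <- peak_period(pg)
  expect_equal(pk$period, 20)          # flat: shortest tested period
  expect_false(pk$significant)
})

test_that("serial periodogram tracks a programmed period step", {
  ts <- synth_series("period_program", days = 30, dt = 15, amplitude = 1,
                     period_schedule = data.frame(time = c(0, 15 * 1440),
                                                  period = c(1440, 1500)))
  spec <- section_spec(10 * 96, 96, 96)
  sp <- serial_periodogram(ts, spec, periods = 88:108,
                           method = "lomb_scargle_floating")
  # below 8 cycles of the longest tested period a warning is raised
  expect_warning(
    serial_periodogram(ts, spec, periods = c(88:108, 130),
                       method = "lomb_scargle_floating"),
    "fewer than 8 cycles")
  expect_equal(nrow(sp$matrix), 21L)
  # early sections at 96 samples (1440 min), late ones at 100 (1500 min)
  expect_equal(sp$peak$period[1], 96)
  expect_equal(sp$peak$period[21], 100)
  # the transition spans at most l/s = 10 sections
  moving <- which(sp$peak$period > 96 & sp$peak$period < 100)
  expect_lte(length(moving), 10)
  expect_true(all(diff(sp$peak$period) >= 0))
  expect_error(serial_periodogram(ts, section_spec(96, 96, 96), 88:108),
               "hard floor")
})

test_that("two close components show twin peaks, merging after a regime change", {
  # 22 days with T = 1380 and 1500 min together (an entrained plus an
  # endogenous component), then 22 days with a single 1440 min rhythm
  n1 <- 22 * 96
  t1 <- 1:n1
  x1 <- cos(2 * pi * t1 / 92) + cos(2 * pi * t1 / 100)
  x2 <- 2 * cos(2 * pi * t1 / 96)
  ts <- rhythm_ts(c(x1, x2), dt = 15)
  spec <- section_spec(20 * 96, 2 * 96, 96)   # 20-day sections, 2-day step
  sp <- serial_periodogram(ts, spec, periods = seq(88, 104, 0.5),
                           method = "lomb_scargle_floating")
  per <- sp$periods
  row1 <- sp$matrix[1, ]
  at <- function(row, p0) row[which.min(abs(per - p0))]
  # both component peaks present in the first section, saddle between them
  expect_gt(at(row1, 92), at(row1, 96))
  expect_gt(at(row1, 100), at(row1, 96))
  # a single intermediate peak after the regime change
  last <- sp$matrix[nrow(sp$matrix), ]
  expect_equal(per[which.max(last)], 96)
})

test_that("false-alarm calibration of the floating LSP threshold", {
  # white noise, N = 500; the 249 Fourier periods N/k are independent tests,
  # so with the Sidak exponent matched to the tested grid the family-wise
  # rate is nominal. 1000 seeded replicates; binomial band [0.02, 0.10].
  set.seed(2718)
  N <- 500; R <- 1000
  periods <- N / (1:249)
  thr <- lsp_threshold(N, p = 0.05, floating = TRUE, m = length(periods))
  Y <- matrix(rnorm(N * R), N, R)
  P <- chronoserial:::.lsp_statistic(Y, 1:N, periods, floating = TRUE)
  rate <- mean(apply(P, 2, max) > thr)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.10)
})
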