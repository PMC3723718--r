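test_that("generators are bit-reproducible under a fixed seed", {
  for (kind in c("sinusoid", "square", "two_component", "pink_noise",
                 "white_noise", "poisson_counts")) {
    a <- synth_series(kind, days = 2, dt = 60, snr = 5, seed = 42)
    b <- synth_series(kind, days = 2, dt = 60, snr = 5, seed = 42)
    expect_identical(a$values, b$values, label = kind)
  }
  # the caller's RNG state is untouched
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(synth_series("white_noise", days = 1, seed = 9))
  expect_identical(runif(1), r1)
})

test_that("sinusoid generator closes the loop with the phase module", {
  ts <- synth_series("sinusoid", days = 10, dt = 60, period = 1440,
                     amplitude = 1, mesor = 2, peak = 8 * 60)
  z <- serial_phase(ts, section_spec(24, 24, 24), "acrophase", track = FALSE)
  expect_equal(z$values, rep(8, 10), tolerance = 1e-6)
})

test_that("square generator: onset, duty cycle and flank recovery", {
  ts <- synth_series("square", days = 5, dt = 60, period = 1440,
                     amplitude = 1, onset = 7 * 60, duty = 0.5)
  m <- matrix(ts$values, nrow = 5, byrow = TRUE)
  expect_equal(unname(colSums(m) > 0),
               ((0:23) >= 7) & ((0:23) < 19))
  f <- flank_squarewave(m[1, ])
  expect_equal(c(f$onset, f$offset), c(8, 20))  # samples 8..19 cover 7-19 h
})

test_that("pink noise has a 1/f spectrum (log-log slope about -1)", {
  ts <- synth_series("pink_noise", days = 20, dt = 15, amplitude = 1,
                     seed = 7)
  x <- ts$values
  N <- length(x)
  pw <- Mod(fft(x - mean(x)))[2:(N / 2)]^2
  fr <- (1:(N / 2 - 1)) / N
  slope <- coef(lm(log(pw) ~ log(fr)))[2]
  expect_gte(slope, -1.2)
  expect_lte(slope, -0.8)
})

test_that("phase program validates its schedule", {
  expect_error(
    synth_series("phase_program", days = 2, dt = 60,
                 shifts = data.frame(time = 10 * 1440, shift = -360)),
    "beyond the series")
})

test_that("series round-trip through CSV is lossless", {
  ts <- synth_series("white_noise", days = 1, dt = 30, amplitude = 2,
                     seed = 12)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_series(ts, path)
  back <- read_series(path)
  expect_equal(back$values, ts$values, tolerance = 1e-12)
  expect_equal(back$dt, ts$dt)
})

test_that("read_series handles layouts, missing dt and non-uniform stamps", {
  p1 <- tempfile(fileext = ".txt"); on.exit(unlink(p1), add = TRUE)
  writeLines(c("1.5", "2.5", "3.5"), p1)
  expect_error(read_series(p1), "'dt'")
  ts <- read_series(p1, dt = 15)
  expect_equal(ts$values, c(1.5, 2.5, 3.5))
  # ISO timestamps
  p2 <- tempfile(fileext = ".csv"); on.exit(unlink(p2), add = TRUE)
  writeLines(c("time,value",
               "2026-01-01T00:00:00,1",
               "2026-01-01T00:15:00,2",
               "2026-01-01T00:30:00,3"), p2)
  ts2 <- read_series(p2)
  expect_equal(ts2$dt, 15)
  expect_equal(ts2$values, 1:3)
  # a gap is rejected with the offending index
  p3 <- tempfile(fileext = ".csv"); on.exit(unlink(p3), add = TRUE)
  writeLines(c("time,value", "0,1", "15,2", "45,3"), p3)
  expect_error(read_series(p3), "non-uniform.*index 3")
})

test_that("actogram and matrix plots render on a null device", {
  ts <- synth_series("sinusoid", days = 10, dt = 60, period = 1440,
                     amplitude = 1, mesor = 2)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  for (pf in 1:3) {
    m <- plot_actogram(ts, plot_factor = pf)
    expect_equal(dim(m), c(10L, 24L))
  }
  z <- serial_phase(ts, section_spec(24, 24, 24), "acrophase")
  expect_silent(plot_actogram(ts, overlay = z))
  sp <- serial_spectrum(ts, section_spec(24, 24, 24), h = 6)
  expect_equal(dim(plot_matrix(sp)), c(10L, 6L))
  spg <- suppressWarnings(
    serial_periodogram(ts, section_spec(120, 24, 24), periods = 20:30,
                       method = "lomb_scargle_floating"))
  expect_silent(plot_matrix(spg, peak = TRUE))
  expect_silent(plot_matrix(matrix(1:6, 2), normalize_rows = TRUE))
})

test_that("CLI subcommands run end to end", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  series <- file.path(dir, "s.csv")
  chronoserial_cli(c("simulate", "--kind", "sinusoid", "--days", "10",
                     "--dt", "60", "--mesor", "2", "--snr", "10",
                     "--seed", "4", "--out", series))
  expect_true(file.exists(series))
  out1 <- file.path(dir, "f.csv")
  chronoserial_cli(c("filter", "--in", series, "--method", "median",
                     "--window", "5", "--out", out1))
  expect_equal(nrow(read.csv(out1)), 240)
  out2 <- file.path(dir, "z.csv")
  chronoserial_cli(c("stat", "--in", series, "--stat", "mean",
                     "--length", "24", "--step", "24", "--period", "24",
                     "--out", out2))
  z <- read.csv(out2)
  expect_equal(nrow(z), 10)
  expect_equal(z$value, rep(2, 10), tolerance = 0.2)
  out3 <- file.path(dir, "ph.csv")
  chronoserial_cli(c("phase", "--in", series, "--method", "acrophase",
                     "--length", "24", "--step", "24", "--period", "24",
                     "--out", out3))
  expect_equal(nrow(read.csv(out3)), 10)
  out4 <- file.path(dir, "pk.csv")
  chronoserial_cli(c("periodogram", "--in", series, "--method", "lsp-float",
                     "--pmin", "1200", "--pmax", "1700",
                     "--section-cycles", "10", "--out", out4))
  pk <- read.csv(out4)
  expect_equal(pk$period_minutes, 1440, tolerance = 0.01)
  out5 <- file.path(dir, "ix.csv")
  chronoserial_cli(c("indices", "--in", series, "--out", out5))
  ix <- read.csv(out5)
  expect_true(ix$RA > 0 && ix$RA <= 1)
  out6 <- file.path(dir, "mk.csv")
  chronoserial_cli(c("wavelet", "--in", series, "--period", "1440",
                     "--out", out6))
  expect_gt(nrow(read.csv(out6)), 5)
  expect_error(chronoserial_cli("nope"), "unknown subcommand")
})
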