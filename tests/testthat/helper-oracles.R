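# Independent brute-force oracles used to freeze expected values.

# every window of length l fitting in N samples on the step grid
enumerate_windows <- function(N, l, s) {
  starts <- integer(0)
  j <- 1L
  repeat {
    a <- (j - 1L) * s + 1L
    if (a + l - 1L > N) break
    starts <- c(starts, a)
    j <- j + 1L
  }
  starts
}

# number of windows (on the step grid) containing a fixed interior sample
count_windows_containing <- function(i, N, l, s) {
  starts <- enumerate_windows(N, l, s)
  sum(starts <= i & i <= starts + l - 1L)
}

# exhaustive search over all circular square templates [c, d)
exhaustive_squarewave <- function(y) {
  n <- length(y)
  best <- c(NA, NA); best_r <- -Inf
  for (c in 1:n) for (d in 1:n) {
    len <- (d - c) %% n
    if (len == 0) next
    q <- as.numeric(((seq_len(n) - c) %% n) < len)
    r <- suppressWarnings(cor(y, q))
    if (!is.na(r) && r > best_r) { best_r <- r; best <- c(c, d) }
  }
  list(c = best[1], d = best[2], r = best_r)
}

# brute-force circular M10/L5 search on a profile
brute_window_means <- function(profile, w) {
  n <- length(profile)
  vapply(seq_len(n), function(s) {
    idx <- ((s - 1 + 0:(w - 1)) %% n) + 1
    mean(profile[idx])
  }, numeric(1))
}

# dominant DFT period of a (mean-removed) series
dominant_dft_period <- function(z) {
  z <- z - mean(z)
  n <- length(z)
  pw <- Mod(fft(z))[2:floor(n / 2)]
  k <- which.max(pw) + 1L
  n / (k - 1L)
}

expect_angle_equal <- function(a, b, tol = 1e-9) {
  d <- (a - b) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  expect_lt(max(abs(d)), tol)
}
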