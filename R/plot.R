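#' Actogram (single, double or triple plot)
#'
#' Raster display of a long record: one row per cycle, rows descending in
#' time, each row showing `plot_factor` consecutive cycles so that drifting
#' phases form continuous diagonals. Serial phase results (onsets,
#' acrophases, wavelet markers) can be overlaid at their within-cycle
#' abscissa.
#'
#' @param ts a [rhythm_ts()].
#' @param period row-folding period in minutes (default 1440).
#' @param plot_factor 1 (single), 2 (double) or 3 (triple) plotted cycles
#'   per row.
#' @param overlay optional `serial_result` of phases in hours within the
#'   cycle (e.g. from [serial_phase()]), drawn as a line over the raster;
#'   or a numeric vector with one value per row.
#' @param col bar colour.
#' @param main plot title (defaults to the series name).
#' @return Invisibly, the matrix of per-row values (rows x samples/cycle).
#' @export
plot_actogram <- function(ts, period = 1440, plot_factor = 2, overlay = NULL,
                          col = "black", main = NULL) {
  stopifnot(inherits(ts, "rhythm_ts"), plot_factor %in% 1:3)
  bins <- period / ts$dt
  if (abs(bins - round(bins)) > 1e-8)
    stop("'period' must be an integer number of samples")
  bins <- as.integer(round(bins))
  nrows <- length(ts$values) %/% bins
  if (nrows < 1L) stop("series shorter than one cycle")
  m <- matrix(ts$values[seq_len(nrows * bins)], nrow = nrows, byrow = TRUE)
  vmax <- max(m, na.rm = TRUE)
  if (!is.finite(vmax) || vmax <= 0) vmax <- 1
  if (is.null(main)) main <- ts$name
  graphics::plot(NULL, xlim = c(0, plot_factor * period / 60),
                 ylim = c(nrows + 1, 0), xlab = "time (h)", ylab = "cycle",
                 main = main, yaxs = "i")
  hrs <- (seq_len(bins) - 1) * ts$dt / 60
  for (r in seq_len(nrows)) {
    for (kk in seq_len(plot_factor)) {
      rr <- r + kk - 1L
      if (rr > nrows) break
      h <- m[rr, ] / vmax * 0.9
      h[is.na(h)] <- 0
      x0 <- (kk - 1) * period / 60 + hrs
      graphics::rect(x0, r, x0 + ts$dt / 60, r - h, col = col, border = NA)
    }
  }
  if (!is.null(overlay)) {
    ph <- if (inherits(overlay, "serial_result")) overlay$values else overlay
    rows <- seq_along(ph)
    graphics::lines(ph %% (period / 60), rows - 0.5, col = "red", lwd = 2)
  }
  invisible(m)
}

#' Heatmap of a serial matrix ("graphic matrix")
#'
#' Displays a sections-by-periods (or sections-by-harmonics) matrix as a
#' heatmap with section 1 at the top, optionally per-row normalized, with an
#' optional peak-track overlay line (the classic red line of serial
#' periodograms).
#'
#' @param m numeric matrix (rows = sections) or a `serial_spectrum` /
#'   `serial_periodogram` object.
#' @param col_values numeric values for the columns (x axis); defaults to
#'   column index.
#' @param normalize_rows rescale each row to max 1?
#' @param peak optional numeric vector (one x-value per row) drawn as an
#'   overlay line; for a `serial_periodogram` the stored peak track is used
#'   when `peak = TRUE`.
#' @param palette colour ramp (default grey scale, dark = high).
#' @param xlab,ylab,main axis labels.
#' @return Invisibly, the plotted matrix.
#' @export
plot_matrix <- function(m, col_values = NULL, normalize_rows = FALSE,
                        peak = NULL, palette = NULL,
                        xlab = "period / harmonic", ylab = "section",
                        main = "") {
  if (inherits(m, "serial_spectrum")) {
    if (is.null(col_values)) col_values <- seq_len(m$h)
    m <- m$power
    if (xlab == "period / harmonic") xlab <- "harmonic"
  } else if (inherits(m, "serial_periodogram")) {
    if (is.null(col_values)) col_values <- m$period_minutes
    if (isTRUE(peak)) peak <- m$peak$period_minutes
    m <- m$matrix
    if (xlab == "period / harmonic") xlab <- "period (min)"
  }
  m <- as.matrix(m)
  if (is.null(col_values)) col_values <- seq_len(ncol(m))
  if (normalize_rows) {
    mx <- apply(m, 1, max, na.rm = TRUE)
    m <- m / ifelse(mx > 0, mx, 1)
  }
  if (is.null(palette)) palette <- grDevices::gray(seq(1, 0, length.out = 64))
  nr <- nrow(m)
  graphics::image(x = col_values, y = seq_len(nr), z = t(m[nr:1, , drop = FALSE]),
                  col = palette, xlab = xlab, ylab = ylab, main = main,
                  yaxt = "n", useRaster = FALSE)
  at <- pretty(seq_len(nr))
  at <- at[at >= 1 & at <= nr]
  graphics::axis(2, at = nr - at + 1, labels = at)
  if (!is.null(peak) && !isFALSE(peak) && is.numeric(peak))
    graphics::lines(peak, nr - seq_along(peak) + 1, col = "red", lwd = 2)
  invisible(m)
}
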