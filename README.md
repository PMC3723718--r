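# chronoserial

Serial section analysis of long biological-rhythm time series in R.

## The problem

Week- to month-long recordings of motor activity, body temperature or other
circadian variables are rarely stationary: phase drifts in constant
darkness, periods split under unusual lighting cycles, amplitude decays with
age. A single whole-record analysis averages all of this away. **Serial
analysis** cuts the record `X = {x_1..x_N}` (sampling interval Δt) into
successive sections of length `l`, displaced by a step `s`, analyzes each in
the circadian range with period `T`, and studies the resulting series
`Z = {z_1..z_n}`, `n = floor((N−l)/s) + 1`, over time. The package is aimed
at chronobiologists analyzing actigraphy-like records and at methodologists
who need the underlying estimators as testable building blocks.

## What is implemented

| Area | Functions |
|---|---|
| Sections & driver | `section_spec`, `segment`, `serial_apply`, `n_sections` |
| Multiplicity | `sidak_per_test`, `bonferroni_per_test`, `effective_multiplicity` |
| Phase unwrapping | `track_phase` (≤ T/2 steps from a k-point extrapolation) |
| Filters | `moving_average`, `moving_median`, `transfer_function`, `dichotomize` |
| Scalar & indices | `serial_scalar`, `intradaily_variability` (IV), `relative_amplitude` (RA, M10, L5), `entrainment_fraction` |
| Angular | `acrophase`, `cog_circular`, `cog_linear`, `serial_phase` |
| Flanks | `flank_heaviside`, `flank_squarewave`, `flank_threshold`, `alpha_duration` |
| Harmonics | `harmonic_fit`, `power_spectrum`, `serial_spectrum`, `dual_period_fit` |
| Periodograms | `sokolove_bushell`, `lomb_scargle` (standard & floating-mean), `lsp_threshold`, `serial_periodogram`, `peak_period` |
| Wavelet | `make_wavelet`, `wavelet_convolve`, `phase_markers`, `wavelet_scan`, `rayleigh_r` |
| Data & I/O | `synth_series`, `read_series`, `write_series`, `write_serial_result` |
| Graphics & CLI | `plot_actogram`, `plot_matrix`, `chronoserial_cli` |

Key statistics, in the field's standard notation:

- Acrophase `φ = atan2(Σ yᵢ sin(2πi/n), Σ yᵢ cos(2πi/n))`, identical to the
  angle of the circular centre of gravity — the wrap-safe centrality
  parameter.
- Sokolove–Bushell `Q_P = K·N·Σ_h(ȳ_h − ȳ)² / Σ_j(y_j − ȳ)²` with percent
  variance `Q_P·100/N`; Lomb–Scargle `P(ω)` with maximum `(N−1)/2`
  (standard) or exactly 1 (generalized floating-mean), with closed-form
  Sidak-corrected thresholds.
- Van Someren indices `IV = N·Σ(yᵢ−yᵢ₋₁)² / ((N−1)·Σ(yᵢ−ȳ)²)` and
  `RA = (M10 − L5)/(M10 + L5)`.
- Moving-average transfer `H(f) = |sin(πfM/2)/(M sin(πf/2))|`, `f = 1` at
  the Nyquist frequency.

## Worked example

A 20-day simulated activity record (Δt = 15 min, mesor 100, amplitude 50,
SNR 10) whose lighting phase is delayed 6 h at day 10; daily acrophase
tracking, a floating-mean Lomb–Scargle periodogram, and non-parametric
indices:

```r
library(chronoserial)

ts <- synth_series("phase_program", days = 20, dt = 15, period = 1440,
                   amplitude = 50, mesor = 100, snr = 10, seed = 11,
                   shifts = data.frame(time = 10 * 1440, shift = -360))
ts
#> <rhythm_ts> 'phase_program' N=1920 dt=15 min (20.00 days)

z <- serial_phase(ts, section_spec(96, 96, 96), method = "acrophase")
round(z$values, 2)
#>  [1] 23.92 24.00 24.02 24.01 24.03 24.03 23.99 24.07 23.97 23.97 17.95 18.00
#> [13] 17.99 18.07 17.98 18.07 18.07 17.91 17.98 17.97

lomb_scargle(ts, periods = seq(80, 112, 1), floating = TRUE)
#> <periodogram> lomb_scargle_floating: 33 periods, N=1920
#>   peak: period 94 samples (1410 min), statistic 0.8317 *

round(intradaily_variability(ts), 3)
#> [1] 0.082
round(relative_amplitude(ts, period = 1440, dt = 15)$RA, 3)
#> [1] 0.306
```

Reading the output: the daily acrophase sits at ~24 h (= 0 h) for ten days,
then steps cleanly to ~18 h — the −6 h programmed shift, reported as a short
jump because `track_phase()` forbids spurious near-full-cycle leaps. Taken
over the *whole* record the periodogram compromises on an intermediate
period (1410 min, significant at the Sidak-corrected 5% level) — exactly the
non-stationarity that motivates analyzing sections serially. IV near 0.08 is
a smooth, unfragmented rhythm; RA of 0.31 reflects the 50/100
amplitude-to-mesor ratio under noise.

`plot_actogram(ts, overlay = z)` draws the double-plotted actogram with the
acrophase track; `plot_matrix(serial_periodogram(...), peak = TRUE)` draws
the serial periodogram heatmap with the peak-period line.

A command-line interface covers the same pipelines
(`inst/cli/chronoserial`):

```sh
chronoserial simulate --kind sinusoid --days 10 --dt 15 --snr 5 --seed 1 --out s.csv
chronoserial phase --in s.csv --method acrophase --length 96 --step 96 --period 96 --out z.csv
chronoserial periodogram --in s.csv --method lsp-float --pmin 960 --pmax 1800 --out peaks.csv
```

## Design notes

See the methods vignette (`vignettes/serial-analysis.Rmd`) for the model,
parameter guidance (section length/step/period, thresholds, wavelet kernel
width), the synthetic generator's stated world, numerical conventions, and
known limitations.
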