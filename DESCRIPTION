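Package: chronoserial
Title: Serial Section Analysis of Long Biological Rhythm Time Series
Version: 0.1.0
Authors@R:
    person("Chronoserial", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the serial (section-by-section) analysis of long,
    uniformly sampled biological-rhythm recordings such as motor activity or
    body temperature. Provides section segmentation with overlap-aware
    multiplicity correction, simple noise filters with their analytic transfer
    function, per-section scalar descriptors and non-parametric indices
    (intradaily variability, relative amplitude), angular phase estimators
    (acrophase, linear and circular centre of gravity, onset/offset flank
    detection), least-squares harmonic spectra and two-close-period models,
    Sokolove-Bushell and Lomb-Scargle periodograms (including the
    floating-mean variant) with significance thresholds and peak tracking,
    sinusoid-Gaussian wavelet convolution for per-cycle phase markers, the
    Rayleigh test for group phase homogeneity, a seeded synthetic-rhythm
    generator, actogram and heatmap graphics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
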