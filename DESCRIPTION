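Package: morwave
Title: Timescale-Specific Spatial Synchrony Analysis with Complex Wavelets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and attributing spatial synchrony in
    spatiotemporal panels of annual time series. Provides complex Morlet
    wavelet transforms on a geometric timescale grid, wavelet mean fields
    and wavelet phasor mean fields with Monte-Carlo significance
    thresholds, timescale-specific spatial coherence with Fourier-surrogate
    hypothesis tests, multivariate wavelet linear models with complex
    timescale-dependent coefficients (including leave-one-out model
    selection, coefficient-phase diagnostics, and spatial permutation
    tests), a wavelet Moran theorem for predicted synchrony and the
    fraction of synchrony explained, and a synchrony attribution theorem
    partitioning explained synchrony into per-driver and driver-interaction
    components. Includes generators for fully specified synthetic
    two-driver scenarios used to validate the methods, and a command-line
    interface over the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
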