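# morwave

Timescale-specific analysis and attribution of spatial synchrony in
ecological (and other) spatiotemporal panels, using complex Morlet
wavelets.

## The problem

Spatially separated populations often fluctuate in step. A classical
explanation is the Moran effect: spatially correlated drivers (climate,
predators) transmit their correlation to the populations they force. Two
features of real systems make this hard to quantify with ordinary
correlations: synchrony is *timescale-specific* (a panel can be synchronous
in its slow components and asynchronous in its fast ones, and correlations
confound the two), and several drivers can act at once with phase lags, so
their effects on synchrony need not add — aligned drivers produce *more*
synchrony than they would independently, misaligned drivers less.

`morwave` is for ecologists and biostatisticians who have `N` annual time
series (locations × years) for a response and for candidate drivers, and
want to know: at which timescales is the response synchronous, which
drivers are associated with it (allowing lags), how much of the observed
synchrony those drivers explain, and how much comes from interactions
*between* drivers.

## The statistics at its core

For the wavelet transform `W_σ(t)` of each location's series (complex
Morlet, timescale grid geometric in `σ`), the package provides:

- **Wavelet mean field (WMF)** `r_σ(t) = (1/N) Σ_n w_{n,σ}(t)` of
  power-normalized transforms, whose magnitude maps synchrony by time and
  timescale; its time-averaged square `{|r_σ(t)|²}_t` is the *mean squared
  synchrony*. The **phasor** variant (WPMF) is bounded by 1 and measures
  pure phase synchrony, with Monte-Carlo significance thresholds against a
  uniform-phase null.
- **Spatial coherence** `Π_σ = |⟨w⁽⁰⁾ conj(w⁽¹⁾)⟩| / sqrt(⟨|w⁽⁰⁾|²⟩⟨|w⁽¹⁾|²⟩)`
  in [0, 1], detecting phase-lagged associations, with Fourier-surrogate
  band p-values.
- **Wavelet linear models**
  `w⁽⁰⁾ ≈ β₁(σ) w⁽¹⁾ + … + β_K(σ) w⁽ᴷ⁾` with complex timescale-dependent
  coefficients (magnitude = strength, argument = lag), plus
  drop-one-predictor surrogate tests, leave-one-location-out model
  selection, coefficient-phase diagnostics, and spatial permutation tests
  for locality.
- **Wavelet Moran theorem**: `{|r_σ⁽⁰⁾|²}_t ≈ {|r_σ⁽ʰ⁾|²}_t |Π_σ⁽⁰ʰ⁾|²` —
  observed synchrony factorizes into model synchrony times squared
  model–response coherence, giving predicted-synchrony surfaces and the
  fraction of band synchrony explained.
- **Synchrony attribution theorem**: the explained fraction decomposes
  exactly into per-driver terms `|β_k|² {|r⁽ᵏ⁾|²}_t` plus interaction
  cross-terms `2 Re[β_j conj(β_k) C_jk]`, positive when drivers reinforce;
  surrogate randomizations (`interaction_randomization()`) probe the same
  interaction empirically.
- A fully specified **synthetic two-driver scenario** (26 locations, 60
  years, 20-year periodicity, 1:3 signal-to-noise combination ratio, a
  5-year-lagged second driver, and a phase parameter `phi` that moves the
  drivers from reinforcing to counteracting) used to validate all of the
  above.

## Worked example

Generate the two-driver scenario at `phi = 0` (reinforcing drivers), fit
the jointly driven population on both drivers, and attribute its
long-timescale synchrony:

```r
library(morwave)

sc <- generate_fig1(phi = 0, seed = 1)
#> <two_driver_scenario> phi = 0.00 (f = 1.5811), 26 locations x 60 years, seed 1

resp  <- panel_transform(sc$gamma3)           # power-normalized transforms
preds <- list(alpha    = panel_transform(sc$alpha),
              beta_lag = panel_transform(sc$beta_lagged))
model <- fit_wlm(resp, preds, band = c(16, 25))
#> <wavelet_model> 2 predictor(s): alpha, beta_lag
#>   band (16, 25] yr; band-mean coherence 0.878

j <- which.min(abs(model$timescales - 20))
Arg(model$betas[, j])
#> alpha: -3.09   beta_lag: 3.13

fraction_explained(model)
#> [1] 0.799

attribute_synchrony(model)
#> <synchrony_partition> band (16, 25]
#>   total explained fraction: 0.7995
#>   alpha: 0.1069
#>   beta_lag: 0.3291
#>   interactions: 0.3635
```

Reading the output: at the construction's dominant 20-year timescale the
fitted coefficients of both drivers have phase ≈ ±π — each was built in
antiphase with the population (the lagged driver is passed already
lagged). The model accounts for ~80% of the population's mean squared
synchrony in the 16–25-year band, and the interaction term — the
reinforcement between the two drivers' synchronous components — contributes
more than either driver alone, which is exactly what this `phi = 0`
construction was designed to show. Re-running with `phi = 1` makes the
interaction fraction negative.

`tidy()`/`glance()` methods give tabular views of models, coherence
profiles and partitions; `autoplot()` draws mean-field heatmaps (with
phase-synchrony significance contours), coherence profiles, and partition
bars. A command-line wrapper over the full workflow (simulate → clean →
transform → mean fields → coherence → model fit/selection → Moran →
attribution → interaction randomization) is installed at
`inst/cli/morwave.R`; see `run_cli()`.

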