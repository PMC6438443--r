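---
title: "Timescale-specific spatial synchrony: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timescale-specific spatial synchrony: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morwave)
```

## The problem

Spatial synchrony — correlated fluctuations of the same ecological variable
at separated locations — is near-ubiquitous in population data, and a
classical explanation is the Moran effect: spatially correlated
environmental (or biotic) drivers transmit their correlation to the
populations they force. Real systems complicate the classical picture in
two ways this package is built around. First, synchrony is
timescale-specific: a panel of annual series can be strongly synchronous in
its slow (multi-year) components and asynchronous in its fast components,
and ordinary correlations confound the two. Second, several drivers can act
at once, possibly with phase lags, and their effects on synchrony need not
add: depending on the phase relationships between the drivers' synchronous
components, joint forcing can produce more (or less) synchrony than the sum
of the individual effects. The package quantifies synchrony by time and
timescale, fits timescale-specific linear models of a response on multiple
drivers with complex coefficients, tests those associations against
surrogate nulls, and partitions band-aggregated synchrony into per-driver
and interaction components.

All inputs are spatiotemporal panels: `N` location series of equal length
`T` on an annual grid (`st_panel`), with `N >= 2`, `T >= 4`, finite values,
and consecutive years.

## Preprocessing

`boxcox_clean()` prepares raw panels. Per location: values are shifted to
positive support when necessary (`-min + 1e-3 * range`; no shift if already
positive), Box-Cox transformed with the exponent maximizing the profile
log-likelihood on a grid (default [-5, 5] in steps of 0.01, wide enough for
count-like ecological data; grid search avoids optimizer brittleness on
short series), linearly detrended against time, and standardized to mean 0
and variance 1 (to 1e-8). The order shift → transform → detrend →
standardize follows standard practice for wavelet preprocessing, where the
transform is applied to stationarized, comparable series. The exponent is
chosen by likelihood rather than a normality statistic; for data already
near-normal the likelihood is flat near 1 and the fitted exponent is only
weakly identified, which is harmless since nearby exponents give nearly
identical transforms.

## The wavelet transform

`morlet_transform()` computes, for each location, the complex Morlet
transform

$$W_\sigma(t) = \sum_u x(u)\,\overline{\psi_{\sigma,t}(u)},\qquad
\psi_{\sigma,t}(u) = \sigma^{-1/2}\pi^{-1/4}
 e^{\,2\pi i f_0 (u-t)/\sigma}\, e^{-(u-t)^2/(2\sigma^2)},$$

with the kernel truncated at `|u - t| > 4 sigma` and computed by direct
convolution (exactness near edges is easy to reason about at these series
lengths; an FFT implementation buys nothing at `T` of a few dozen). The
magnitude and argument of `W` give the strength and phase of oscillations
of period `sigma` at time `t`.

Tunable parameters, with defaults and reasons:

* `f0 = 1` (central frequency): makes the peak-response timescale of a pure
  sinusoid equal its period, so `sigma` reads directly as a period in
  years.
* Timescale grid: geometric with ratio `1.05`, from `sigma_min = 2` years
  (the annual Nyquist limit) to `sigma_max = T/2`. A geometric grid gives
  equal weight per log-timescale, matching how band statistics are
  aggregated.
* Cone of influence: a cell is flagged when the series edges clip at least
  1% of the truncated kernel's squared norm. Flagged cells are kept, not
  deleted — surfaces are displayed in full and the flag controls which
  cells enter time-averaged statistics.

Transforms are computed on centred series: the transform subtracts each
location's mean rather than rejecting inputs with nonzero means. Centring
is linear and idempotent on cleaned data, so cleaned inputs are unaffected,
while valid constructions whose sample means are merely close to zero (any
finite draw of a zero-mean process) are handled without a spurious error.

A consequence of the edge rule worth stating explicitly: at timescales
above roughly `T/3`, every time point is within the flagged edge region
(the kernel half-width exceeds the distance to the nearest edge for all
`t`). Time-averaged statistics therefore use non-flagged cells where any
exist at a timescale and fall back to averaging over all cells at
timescales where none do. The alternative — dropping those timescales
entirely — would silently remove the long-timescale band that the methods
exist to analyze for series of the length considered here. Long-timescale
values should nevertheless be read with the usual caution about edge
effects.

Two normalizations (`normalize_transforms()`) feed the downstream
statistics: *phasor* (unit magnitude per cell; pure phase information) and
*power* (each location scaled so its mean squared magnitude over all cells
is 1, preserving the relative distribution of power across timescales).

## Mean fields and significance

The wavelet mean field (`wmf()`) averages power-normalized transforms
across locations, $r_\sigma(t) = \tfrac1N\sum_n w_{n,\sigma}(t)$;
synchronous components reinforce while incoherent components cancel at rate
$1/\sqrt N$, so the magnitude surface displays synchrony by time and
timescale. The time average of $|r_\sigma(t)|^2$ is the *mean squared
synchrony* profile, and `mean_squared_synchrony()` aggregates it over a
band with equal weight per grid timescale. The wavelet phasor mean field
(`wpmf()`) does the same with phasor-normalized transforms; its magnitude
lies in [0, 1], equals 1 exactly at cells where all locations share a
phase, and measures pure phase synchrony.

Phase synchrony is significance-tested against the null of independent
uniform phases: `wpmf_thresholds()` estimates upper quantiles of the
magnitude of a mean of `N` unit phasors by Monte Carlo (default 10,000
draws, seeded; for `N` not tiny the Rayleigh limit
$\sqrt{-\log\alpha / N}$ is an accurate approximation, which the tests use
as an oracle). Thresholds are pointwise per cell, with no multiple-testing
correction — contour displays are exploratory, and band-level inference is
done with surrogate tests instead.

## Coherence and Fourier surrogates

The spatial coherence of two variables at timescale `sigma`,

$$\Pi_\sigma = \frac{\bigl|\langle w^{(0)}\overline{w^{(1)}}\rangle_{n,t}\bigr|}
{\sqrt{\langle |w^{(0)}|^2\rangle\,\langle |w^{(1)}|^2\rangle}},$$

lies in [0, 1] by Cauchy–Schwarz (the per-timescale normalization is chosen
precisely so the bound is exact) and detects consistent associations even
when they are phase-lagged, which ordinary correlations miss. The argument
of the numerator is the typical phase by which the first variable leads the
second.

Significance uses Fourier surrogates (`fourier_surrogates()`): multiply
positive-frequency DFT coefficients by random unit phasors, symmetrize,
invert. Zero and Nyquist coefficients are left untouched (they are real),
so each surrogate preserves the original periodogram magnitudes, mean and
variance exactly. Drawing phases independently per location destroys
spatial synchrony; drawing one shared phase vector per surrogate preserves
every within-variable cross-spectrum — the variable's own synchrony
structure — while destroying its relationship to anything else. These
*synchrony-preserving* surrogates are the null for association tests:
randomization happens in the time domain and surrogates are re-transformed,
so the null preserves exact spectral structure. Band-level p-values
aggregate coherence over grid timescales in the band by unweighted mean
first, then rank the observed statistic among surrogate statistics with the
+1 correction, `p = (1 + #{surrogate >= observed})/(1 + count)`
(mean-then-rank; the default bands split at 4 years, the boundary between
persistent and anti-persistent annual dynamics).

## Wavelet linear models

`fit_wlm()` fits, at every timescale,

$$w^{(0)}_{n,\sigma}(t) \approx \beta_1(\sigma)\,w^{(1)}_{n,\sigma}(t) +
\cdots + \beta_K(\sigma)\,w^{(K)}_{n,\sigma}(t),$$

by complex least squares over stacked location-time cells. The normal
equations carry a ridge jitter of 1e-10 on the Gram diagonal purely for
numerical definiteness; a condition number above 1e10 after jitter raises
an error naming the collinear predictors, because silently near-singular
fits would corrupt the downstream attribution. Least squares maximizes the
coherence between response and fitted combination, so the fitted model's
coherence dominates every single predictor's coherence (asserted in the
test suite). A complex coefficient per timescale is the natural way to
encode a driver's strength *and* lag: an antiphase driver has coefficient
phase near pi, a quarter-cycle-delayed driver near pi/2.

Model assessment and selection:

* `drop_predictor_test()`: the dropped predictor's time-domain series is
  replaced by synchrony-preserving surrogates, re-transformed, and the full
  model refitted (surrogating the dropped predictor — rather than the
  retained ones — matches the logic that the null removes that predictor's
  relationships while retaining everything else).
* `loo_cv_score()`: leave-one-out cross validation with the location as
  the held-out unit — locations are the exchangeable replicates of the
  stacked fit. The score is one minus the held-out squared error relative
  to the held-out response power, accumulated over band cells.
* `select_models()`: exhaustive enumeration of predictor subsets up to
  `max_k` (default cap 5; enumeration is affordable because candidate sets
  are small and greedy search can miss interacting pairs), retaining
  subsets whose members all survive their drop tests at `alpha` (default
  0.05, surrogate count default 1000) and ranking by cross-validated
  score; subsets within 90% of the top score are flagged as competitive.
* `phase_diagnostic()`: compares the coefficient phase to the mean
  empirical cross-phase, two estimators of the same lag that should agree
  for genuine consistent associations.
* `spatial_shuffle_test()`: permutes the predictor's location labels to
  test whether associations are local (as a Moran driver acting in place
  must be) rather than an artifact of spatially averaged association.

## The wavelet Moran theorem and attribution

Write $r^{(h)}_\sigma(t)$ for the mean field of the fitted model (equal to
$\sum_k \beta_k(\sigma) r^{(k)}_\sigma(t)$ by linearity — both routes are
computed and must agree to 1e-10). If the modeled drivers are the only
synchronizing influences, the observed mean squared synchrony approximately
factorizes as

$$\{|r^{(0)}_\sigma(t)|\}_t \approx
\{|r^{(h)}_\sigma(t)|\}_t\,\bigl|\Pi^{(0h)}_\sigma\bigr|^2,$$

with equality exact when the response equals the fit; additional
unmodeled synchronizers push the left side above the right.
`predicted_synchrony()` displays
$|\Pi^{(0h)}_\sigma|\,|r^{(h)}_\sigma(t)|$, and `fraction_explained()`
aggregates the factorization over a band (equal weight per grid timescale)
into a single explained fraction.

Expanding $|r^{(h)}|^2$ with $r^{(h)} = \sum_k \beta_k r^{(k)}$ gives the
attribution decomposition

$$\{|r^{(h)}_\sigma|^2\}_t = \sum_k |\beta_k|^2\,\{|r^{(k)}_\sigma|^2\}_t +
\sum_{j<k} 2\,\mathrm{Re}\bigl[\beta_j\overline{\beta_k}\,C_{jk}(\sigma)\bigr],$$

with $C_{jk}$ the time-mean of $r^{(j)}\overline{r^{(k)}}$ over the same
cells as the mean squared synchrony. `attribute_synchrony()` scales each
band-aggregated term by the same machinery as `fraction_explained()`, so
per-driver fractions plus the interaction fraction sum to the total
explained fraction *by construction* (conservation to 1e-8 is asserted in
the tests). The cross terms are the interaction effects: positive when the
drivers' mean fields reinforce, negative when they counteract.

`interaction_randomization()` probes the same question empirically:
surrogate one predictor's series (shared-phase: keeps its own synchrony,
breaks alignment with the other drivers; independent-phase: breaks both),
rebuild the model mean field *with the original coefficients*, and compare
band mean squared model synchrony. Coefficients are retained rather than
refitted because the quantity of interest is the alignment between
drivers, not the fit; `zero_beta = TRUE` exposes the separate question of
removing the predictor's contribution entirely.

## The synthetic study conditions

`generate_fig1()` generates the fully specified two-driver construction the
package is validated on: 26 locations, 60 years, drivers
$\alpha = \sqrt{1/4}\,\sqrt2\sin(wt) + \sqrt{3/4}\,\varepsilon$ and
$\beta = \sqrt{1/4}\,\sqrt2\cos(wt - \varphi\pi) + \sqrt{3/4}\,\varepsilon'$
with $w = 2\pi/20$, so each driver's synchronous sinusoid carries exactly
1/4 of its variance (a 1:3 combination ratio; the weights are square roots
of the variance fractions, as the stated variance budget forces). Three
populations are driven by $-\alpha(t)$, by $-\beta(t-5)$ (a 5-year lag,
one quarter cycle), and by $-(\alpha(t) + \beta(t-5))/f$ with
$f = \sqrt{2 + \tfrac12\cos(\varphi\pi)}$ normalizing the joint signal to
unit variance; each population mixes its signal with fresh noise in the
same 1:3 ratio. At $\varphi = 0$ the sine and the lagged, negated cosine
reinforce exactly, and the joint population is more synchronous than either
singly driven population; the interaction changes sign as $\varphi$ crosses
0.5 — the calibration fact that quarter-cycle-shifted sinusoids are
uncorrelated. The pre-sample years the lag requires take their synchronous
part from the formula and fresh local noise (any stationary choice works;
this one keeps the generator simple). One master seed seeds the generator
once and fields are drawn in a fixed order, so the same seed reproduces a
scenario bitwise.

`generate_ar1_moran()` provides the classical single-timescale check — an
AR(1) population whose cross-location correlation must equal that of its
driving noise — and `generate_sync_panel()` generalizes the construction
(arbitrary period, synchronous fraction, lag, phase) for property tests.

What the generator deliberately does not emulate: sampling noise of real
plankton surveys, missing observations, spatially structured (distance-
decaying) noise correlation, non-Gaussian marginals, or drivers with
broadband spectra. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated conditions, not robustness to every
feature of field data; the Box-Cox cleaning step and the surrogate
framework are the package's concessions to the latter.

Problem sizes used in the validation suite are those of the construction
(26 locations, 60 years) with 20–50 realisations per stochastic check, and
smaller panels with coarser timescale grids where a property does not
depend on scale; the calibration of the band p-value uses 200 replicates
of 5-location panels with 120 surrogates each.

## Numerical choices and degenerate inputs

* Ridge jitter 1e-10; collinearity is a hard error above condition 1e10.
* Phasor normalization maps exact-zero cells to 0 (they carry no phase);
  power normalization rejects all-zero locations.
* Constant series are rejected by name at cleaning.
* Band aggregation is an unweighted mean over grid timescales inside
  `(lo, hi]`; on the geometric grid this is equal weight per
  log-timescale. Bands that contain no grid point raise an error rather
  than silently returning nothing.
* Surrogate p-values carry the +1 correction and so are never 0; the
  smallest attainable p is `1/(count + 1)`.
* All Monte-Carlo procedures take explicit integer seeds; identical seeds
  give identical results.

## Known limitations

* Annual, equally spaced, complete panels only; missing data are rejected
  rather than imputed.
* The edge-cell fallback at the longest timescales (above) trades
  principled exclusion for availability; conclusions that hinge on the
  longest fifth of the timescale axis deserve independent checking.
* Pointwise phase-synchrony contours carry no multiple-testing control.
* Amplitude-adjusted surrogate variants are not provided; the cleaning
  step is assumed to have normalized marginals before surrogate testing.
* The attribution decomposition concerns mean fields aggregated over
  locations; it does not resolve which location pairs carry the synchrony.
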