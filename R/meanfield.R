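new_mean_field <- function(values, kind, timescales, coi) {
  s <- length(timescales)
  msq <- vapply(seq_len(s), function(j) {
    inc <- included_times(coi, j)
    mean(Mod(values[inc, j])^2)
  }, numeric(1))
  structure(
    list(values = values, kind = kind, timescales = timescales,
         msq = msq, coi = coi),
    class = "mean_field"
  )
}

#' Wavelet mean field (WMF)
#'
#' Averages power-normalized wavelet transforms across locations:
#' `r(t, sigma) = (1/N) * sum_n w_n(t, sigma)`. The magnitude surface
#' `|r|` displays the strength of spatial synchrony by time and timescale;
#' unlike the phasor mean field it is not bounded by 1.
#'
#' The per-timescale element `msq` is the time average of `|r|^2` over
#' cells outside the cone of influence (all cells where no time at a
#' timescale escapes the cone), the *mean squared synchrony* profile.
#'
#' @param normalized A power-normalized `"normalized_set"` (see
#'   [normalize_transforms()]).
#' @return An object of class `"mean_field"`: `values` (complex `T x S`),
#'   `kind` (`"wmf"`), `timescales`, `msq` (length `S`), `coi`.
#' @export
wmf <- function(normalized) {
  if (!inherits(normalized, "normalized_set")) stop("expected a `normalized_set`")
  if (normalized$normalization != "power") {
    stop("wmf requires power normalization (got phasor)")
  }
  vals <- apply(normalized$coefficients, c(2, 3), mean)
  new_mean_field(vals, "wmf", normalized$timescales, normalized$coi)
}

#' Wavelet phasor mean field (WPMF)
#'
#' Averages unit-magnitude (phasor-normalized) transforms across
#' locations. Its magnitude lies in `[0, 1]` and equals 1 exactly where
#' all locations share the same phase, so it measures pure phase
#' synchrony and can be significance-tested against a uniform-phase null
#' ([wpmf_thresholds()]).
#'
#' @param normalized A phasor-normalized `"normalized_set"`.
#' @return A `"mean_field"` of kind `"wpmf"`.
#' @export
wpmf <- function(normalized) {
  if (!inherits(normalized, "normalized_set")) stop("expected a `normalized_set`")
  if (normalized$normalization != "phasor") {
    stop("wpmf requires phasor normalization (got power)")
  }
  vals <- apply(normalized$coefficients, c(2, 3), mean)
  new_mean_field(vals, "wpmf", normalized$timescales, normalized$coi)
}

#' @export
print.mean_field <- function(x, ...) {
  cat(sprintf(
    "<mean_field> kind = %s, %d years x %d timescales; peak msq %.3f at sigma = %.2f\n",
    x$kind, nrow(x$values), length(x$timescales),
    max(x$msq), x$timescales[which.max(x$msq)]
  ))
  invisible(x)
}

#' Mean-field surface in long (tidy) form
#'
#' @param x A `"mean_field"`.
#' @param ... Unused.
#' @return Data frame with columns `time_index`, `timescale`, `magnitude`,
#'   `phase`, `coi`.
#' @export
tidy.mean_field <- function(x, ...) {
  tt <- nrow(x$values)
  s <- length(x$timescales)
  data.frame(
    time_index = rep(seq_len(tt), times = s),
    timescale = rep(x$timescales, each = tt),
    magnitude = as.vector(Mod(x$values)),
    phase = as.vector(Arg(x$values)),
    coi = as.vector(x$coi)
  )
}

#' Monte-Carlo significance thresholds for the wavelet phasor mean field
#'
#' Under the null hypothesis of no phase association among the `N`
#' locations, a WPMF cell is the mean of `N` independent unit phasors
#' with uniform phases. Thresholds are upper quantiles of the magnitude
#' of that mean, estimated by Monte Carlo.
#'
#' @param n_locations Number of locations `N` (>= 2).
#' @param levels Significance levels, each in (0, 1). Default the
#'   0.1/0.05/0.01/0.001 contour levels used for display.
#' @param n_draws Monte-Carlo sample size (default 10000; a warning is
#'   issued below 1000).
#' @param seed Integer seed.
#' @return Object of class `"wpmf_thresholds"`: `levels`, `thresholds`
#'   (magnitude threshold per level), `n_locations`, `n_draws`, `seed`.
#' @export
wpmf_thresholds <- function(n_locations, levels = c(0.1, 0.05, 0.01, 0.001),
                            n_draws = 10000, seed = 1) {
  if (n_locations < 2) stop("need at least 2 locations")
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie in (0, 1)")
  if (n_draws < 1000) warning("n_draws < 1000: thresholds will be noisy")
  set.seed(seed)
  u <- matrix(stats::runif(n_draws * n_locations, 0, 2 * pi), n_draws)
  mag <- Mod(rowMeans(exp(1i * u)))
  structure(
    list(
      levels = levels,
      thresholds = stats::quantile(mag, 1 - levels, names = FALSE),
      n_locations = n_locations, n_draws = n_draws, seed = seed
    ),
    class = "wpmf_thresholds"
  )
}

#' @export
print.wpmf_thresholds <- function(x, ...) {
  cat(sprintf("<wpmf_thresholds> N = %d, %d draws\n", x$n_locations, x$n_draws))
  print(data.frame(level = x$levels, threshold = x$thresholds))
  invisible(x)
}

#' Band-aggregated mean squared synchrony
#'
#' Averages a mean field's per-timescale mean squared magnitude over the
#' grid timescales falling in a band, with equal weight per grid point
#' (equal weight per log-timescale on the geometric grid).
#'
#' @param surface A `"mean_field"`.
#' @param band Numeric length-2 interval `(lo, hi]` in years.
#' @return The band mean of `msq` (a single number).
#' @export
mean_squared_synchrony <- function(surface, band) {
  if (!inherits(surface, "mean_field")) stop("expected a `mean_field`")
  j <- band_indices(surface$timescales, band)
  mean(surface$msq[j])
}

band_indices <- function(timescales, band) {
  if (length(band) != 2 || band[1] >= band[2]) stop("band must be (lo, hi) with lo < hi")
  j <- which(timescales > band[1] & timescales <= band[2])
  if (length(j) == 0) stop("band contains no grid timescales")
  j
}
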