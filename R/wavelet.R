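#' Geometric timescale grid
#'
#' @param sigma_min,sigma_max Smallest and largest timescale (years).
#' @param spacing Ratio between successive grid timescales (> 1).
#' @return Numeric vector of timescales `sigma_min * spacing^(0:J)`, the
#'   largest not exceeding `sigma_max`.
#' @export
timescale_grid <- function(sigma_min = 2, sigma_max, spacing = 1.05) {
  if (spacing <= 1) stop("`spacing` must exceed 1")
  if (sigma_min <= 0 || sigma_max <= sigma_min) stop("invalid timescale bounds")
  jmax <- floor(log(sigma_max / sigma_min) / log(spacing) + 1e-12)
  sigma_min * spacing^(0:jmax)
}

#' Complex Morlet wavelet transform of a spatiotemporal panel
#'
#' Transforms each location's series with a complex Morlet wavelet on a
#' geometric grid of timescales. The analyzing wavelet centred at time `t`
#' with timescale `sigma` is
#' `psi(u) = sigma^(-1/2) * pi^(-1/4) * exp(2i*pi*f0*(u - t)/sigma) *
#' exp(-(u - t)^2 / (2*sigma^2))`,
#' truncated at `|u - t| > 4*sigma`, and the coefficient is
#' `W(t) = sum_u x(u) * Conj(psi(u))`. With the default central frequency
#' `f0 = 1`, the peak-response timescale of a pure sinusoid equals its
#' period, so `sigma` reads directly as an oscillation period in years.
#'
#' Cells where the series edges clip at least 1% of the truncated kernel's
#' L2 norm are flagged in `coi`, the cone-of-influence mask; flagged cells
#' are retained in the transform (edge effects are flagged, not deleted).
#'
#' @param series A cleaned [st_panel()] (each location mean approximately
#'   0; see [boxcox_clean()]).
#' @param sigma_min,sigma_max Timescale bounds in years, within
#'   `[2, T/2]`. `sigma_max` defaults to `T/2`.
#' @param spacing Geometric grid ratio, default 1.05.
#' @param f0 Central frequency of the Morlet wavelet, default 1.
#'
#' @return An object of class `"wavelet_set"`: list with `coefficients`
#'   (complex `N x T x S` array), `timescales` (length `S`), `f0`, `coi`
#'   (logical `T x S` matrix, identical across locations), and `series`
#'   (the input panel, retained for surrogate-based resampling).
#'
#' @examples
#' p <- st_panel(matrix(rnorm(2 * 40), 2, 40))
#' w <- morlet_transform(boxcox_clean(p)$series)
#' dim(w$coefficients)
#' @export
morlet_transform <- function(series, sigma_min = 2, sigma_max = NULL,
                             spacing = 1.05, f0 = 1) {
  stopifnot_panel(series)
  x <- series$values
  n <- nrow(x)
  tt <- ncol(x)
  if (is.null(sigma_max)) sigma_max <- tt / 2
  if (f0 <= 0) stop("`f0` must be positive")
  if (sigma_min < 2 || sigma_max > tt / 2 || sigma_min >= sigma_max) {
    stop("timescale bounds must satisfy 2 <= sigma_min < sigma_max <= T/2")
  }
  x <- x - rowMeans(x)   # the transform is defined on centred series
  sigmas <- timescale_grid(sigma_min, sigma_max, spacing)
  s <- length(sigmas)
  coef <- array(0 + 0i, dim = c(n, tt, s))
  coi <- matrix(FALSE, tt, s)
  tm <- seq_len(tt)
  for (j in seq_len(s)) {
    sig <- sigmas[j]
    h <- floor(4 * sig)
    d <- outer(tm, tm, "-")            # d[u, t] = u - t
    keep <- abs(d) <= h
    env2 <- exp(-d^2 / sig^2) * keep   # squared magnitude envelope (unscaled)
    psi <- (sig^(-0.5) * pi^(-0.25)) *
      exp(complex(imaginary = 2 * pi * f0 * d / sig)) *
      exp(-d^2 / (2 * sig^2)) * keep
    coef[, , j] <- x %*% Conj(psi)
    # L2 of the truncated kernel with / without edge clipping
    full <- sum(exp(-(seq(-h, h))^2 / sig^2))
    avail <- colSums(env2)
    coi[, j] <- avail < 0.99 * full
  }
  structure(
    list(
      coefficients = coef, timescales = sigmas, f0 = f0, coi = coi,
      series = series
    ),
    class = "wavelet_set"
  )
}

#' @export
print.wavelet_set <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf(
    "<wavelet_set> %d locations x %d years x %d timescales [%.2f, %.2f], f0 = %g\n",
    d[1], d[2], d[3], min(x$timescales), max(x$timescales), x$f0
  ))
  invisible(x)
}

#' Normalize wavelet transforms for mean-field and coherence analysis
#'
#' Two normalizations are available. `"phasor"` divides each coefficient
#' by its own magnitude, retaining only phase information (zero cells map
#' to 0). `"power"` divides each location's coefficients by the square
#' root of that location's mean squared magnitude over all time-timescale
#' cells, so every location has unit mean power while relative power
#' across timescales is preserved.
#'
#' @param transforms A `"wavelet_set"` from [morlet_transform()].
#' @param method `"phasor"` or `"power"`.
#' @return An object of class `"normalized_set"`: as the input, plus a
#'   `normalization` field.
#' @export
normalize_transforms <- function(transforms, method = c("power", "phasor")) {
  if (!inherits(transforms, "wavelet_set")) stop("expected a `wavelet_set`")
  method <- match.arg(method)
  coef <- transforms$coefficients
  n <- dim(coef)[1]
  if (method == "phasor") {
    m <- Mod(coef)
    m[m == 0] <- 1
    coef <- coef / m
  } else {
    for (i in seq_len(n)) {
      mp <- mean(Mod(coef[i, , ])^2)
      if (mp == 0) {
        stop(sprintf("all-zero transform at location '%s': cannot power-normalize",
                     transforms$series$location_ids[i]))
      }
      coef[i, , ] <- coef[i, , ] / sqrt(mp)
    }
  }
  structure(
    list(
      coefficients = coef, timescales = transforms$timescales,
      f0 = transforms$f0, coi = transforms$coi,
      series = transforms$series, normalization = method
    ),
    class = "normalized_set"
  )
}

#' @export
print.normalized_set <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf(
    "<normalized_set> (%s) %d locations x %d years x %d timescales\n",
    x$normalization, d[1], d[2], d[3]
  ))
  invisible(x)
}

#' Transform of a cleaned panel, normalized in one step
#'
#' Convenience composition of [morlet_transform()] and
#' [normalize_transforms()].
#'
#' @inheritParams morlet_transform
#' @inheritParams normalize_transforms
#' @return A `"normalized_set"`.
#' @export
panel_transform <- function(series, method = "power", sigma_min = 2,
                            sigma_max = NULL, spacing = 1.05, f0 = 1) {
  normalize_transforms(
    morlet_transform(series, sigma_min, sigma_max, spacing, f0),
    method
  )
}

# Time indices entering time-averaged statistics at timescale column j:
# non-COI times where any exist, otherwise all times (at the longest
# timescales of short series every cell is edge-affected; excluding them
# all would leave the statistic undefined there).
included_times <- function(coi, j) {
  ok <- !coi[, j]
  if (!any(ok)) ok[] <- TRUE
  ok
}

check_compatible <- function(a, b) {
  if (!identical(dim(a$coefficients), dim(b$coefficients)) ||
      max(abs(a$timescales - b$timescales)) > 1e-10) {
    stop("transform sets have mismatched dimensions or timescale grids")
  }
  invisible(TRUE)
}
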