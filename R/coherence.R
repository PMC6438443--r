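#' Timescale-specific spatial coherence between two variables
#'
#' For power-normalized transform sets `w0`, `w1` of two spatiotemporal
#' variables on the same locations, years and timescale grid, the spatial
#' coherence at timescale `sigma` is
#' `Pi = |mean(w0 * Conj(w1))| / sqrt(mean|w0|^2 * mean|w1|^2)`,
#' the means running over the same location-time cells (outside the cone
#' of influence). `Pi` lies in `[0, 1]` by Cauchy-Schwarz; high values
#' indicate a consistent (possibly phase-lagged) association at that
#' timescale. `cross_phase` is the argument of the numerator mean: the
#' typical phase by which `w0` leads `w1`.
#'
#' @param w0,w1 Power-normalized `"normalized_set"` objects with matching
#'   dimensions and grids.
#' @return Object of class `"coherence"`: data-frame-backed with fields
#'   `timescales`, `pi` (coherence per timescale), `cross_phase`, plus
#'   `surrogate_quantiles` and `band_pvalues` (NULL here; filled by
#'   [coherence_test()]).
#' @export
spatial_coherence <- function(w0, w1) {
  for (w in list(w0, w1)) {
    if (!inherits(w, "normalized_set") || w$normalization != "power") {
      stop("spatial coherence requires power-normalized transform sets")
    }
  }
  check_compatible(w0, w1)
  s <- length(w0$timescales)
  pi_vec <- phase_vec <- numeric(s)
  for (j in seq_len(s)) {
    inc <- included_times(w0$coi, j)
    a <- w0$coefficients[, inc, j]
    b <- w1$coefficients[, inc, j]
    num <- mean(a * Conj(b))
    den <- sqrt(mean(Mod(a)^2) * mean(Mod(b)^2))
    pi_vec[j] <- Mod(num) / den
    phase_vec[j] <- Arg(num)
  }
  structure(
    list(
      timescales = w0$timescales, pi = pi_vec, cross_phase = phase_vec,
      surrogate_quantiles = NULL, band_pvalues = NULL
    ),
    class = "coherence"
  )
}

#' @export
print.coherence <- function(x, ...) {
  cat(sprintf(
    "<coherence> %d timescales; max Pi %.3f at sigma = %.2f\n",
    length(x$timescales), max(x$pi), x$timescales[which.max(x$pi)]
  ))
  if (!is.null(x$band_pvalues)) {
    for (nm in names(x$band_pvalues)) {
      cat(sprintf("  band %s: p = %.4g\n", nm, x$band_pvalues[[nm]]))
    }
  }
  invisible(x)
}

#' Coherence profile in long (tidy) form
#'
#' @param x A `"coherence"` object.
#' @param ... Unused.
#' @return Data frame with columns `timescale`, `coherence`,
#'   `cross_phase`, and any surrogate quantile curves.
#' @export
tidy.coherence <- function(x, ...) {
  out <- data.frame(
    timescale = x$timescales, coherence = x$pi, cross_phase = x$cross_phase
  )
  if (!is.null(x$surrogate_quantiles)) {
    out <- cbind(out, as.data.frame(x$surrogate_quantiles))
  }
  out
}

#' Fourier surrogates of a spatiotemporal panel
#'
#' Phase-randomized surrogates obtained by multiplying each positive
#' discrete-Fourier frequency coefficient by a random unit phasor,
#' conjugate-symmetrizing and inverting; the zero and (for even `T`)
#' Nyquist coefficients are left untouched (they are real). Each
#' surrogate location series therefore retains exactly the original
#' periodogram magnitudes, sample mean and variance.
#'
#' Two kinds are available. `"fourier_independent"` draws phases
#' independently per location, destroying spatial synchrony.
#' `"fourier_synchrony_preserving"` applies one shared phase draw to all
#' locations, preserving all within-variable cross-spectra (hence the
#' variable's own synchrony) while destroying its relationship with any
#' other variable; these are the *spatially synchronous surrogates* used
#' in nested-model and interaction tests.
#'
#' @param series A cleaned [st_panel()].
#' @param count Number of surrogates (>= 1).
#' @param kind `"fourier_synchrony_preserving"` or
#'   `"fourier_independent"`.
#' @param seed Integer seed.
#' @return List of `count` [st_panel()] objects.
#' @export
fourier_surrogates <- function(series, count,
                               kind = c("fourier_synchrony_preserving",
                                        "fourier_independent"),
                               seed = 1) {
  stopifnot_panel(series)
  kind <- match.arg(kind)
  if (count < 1) stop("`count` must be >= 1")
  x <- series$values
  n <- nrow(x)
  tt <- ncol(x)
  if (tt < 4) stop("need at least 4 time steps for Fourier surrogates")
  fx <- t(apply(x, 1, stats::fft))          # n x tt, row = location spectrum
  # indices (1-based) of freq bins: 1 = zero; for even tt, tt/2 + 1 = Nyquist
  pos <- 2:ceiling((tt + 1) / 2)            # positive, non-Nyquist frequencies
  has_nyq <- tt %% 2 == 0
  set.seed(seed)
  lapply(seq_len(count), function(r) {
    rot <- matrix(1 + 0i, n, tt)
    if (kind == "fourier_synchrony_preserving") {
      ph <- stats::runif(length(pos), 0, 2 * pi)
      phm <- matrix(ph, n, length(pos), byrow = TRUE)
    } else {
      phm <- matrix(stats::runif(n * length(pos), 0, 2 * pi), n)
    }
    rot[, pos] <- exp(1i * phm)
    # conjugate symmetry: bin tt + 2 - k mirrors bin k
    rot[, tt + 2 - pos] <- Conj(rot[, pos])
    if (has_nyq) rot[, tt / 2 + 1] <- 1
    xs <- t(apply(fx * rot, 1, function(row) Re(stats::fft(row, inverse = TRUE)) / tt))
    st_panel(xs, series$location_ids, series$years)
  })
}

#' Rank-based surrogate p-value for a band statistic
#'
#' One-sided p-value of an observed statistic against surrogate draws,
#' with the +1 correction `p = (1 + #{surrogate >= observed}) / (1 + count)`
#' so that p is never 0.
#'
#' @param observed Observed statistic (a single number, e.g. the mean of
#'   a coherence profile over a timescale band).
#' @param surrogate_stats Numeric vector of the same statistic computed
#'   on >= 100 surrogates.
#' @return The p-value.
#' @export
band_pvalue <- function(observed, surrogate_stats) {
  if (length(surrogate_stats) < 100) {
    stop("need at least 100 surrogate statistics")
  }
  (1 + sum(surrogate_stats >= observed)) / (1 + length(surrogate_stats))
}

#' Spatial coherence with Fourier-surrogate significance
#'
#' Computes the coherence profile between two cleaned panels and tests
#' the band-mean coherence in each requested timescale band against
#' synchrony-preserving Fourier surrogates of the second variable: the
#' surrogate destroys the cross-variable relationship while keeping each
#' variable's own spectral and synchrony structure, so large observed
#' band-mean coherence indicates a genuine association.
#'
#' @param x0,x1 Cleaned [st_panel()] objects on the same locations/years.
#' @param bands Named list of length-2 numeric bands, default
#'   `list(short = c(2, 4), long = c(4, T/2))`.
#' @param count Number of surrogates (default 1000).
#' @param seed Integer seed.
#' @param quantiles Probabilities for per-timescale surrogate quantile
#'   curves.
#' @inheritParams morlet_transform
#' @return A `"coherence"` object with `surrogate_quantiles` (matrix,
#'   timescale by probability) and `band_pvalues` filled in.
#' @export
coherence_test <- function(x0, x1, bands = NULL, count = 1000, seed = 1,
                           quantiles = c(0.5, 0.95, 0.99),
                           sigma_min = 2, sigma_max = NULL, spacing = 1.05,
                           f0 = 1) {
  w0 <- panel_transform(x0, "power", sigma_min, sigma_max, spacing, f0)
  w1 <- panel_transform(x1, "power", sigma_min, sigma_max, spacing, f0)
  obs <- spatial_coherence(w0, w1)
  if (is.null(bands)) {
    bands <- list(short = c(2, 4), long = c(4, max(w0$timescales)))
  }
  surr <- fourier_surrogates(x1, count, "fourier_synchrony_preserving", seed)
  sp <- vapply(surr, function(p) {
    ws <- panel_transform(p, "power", sigma_min, sigma_max, spacing, f0)
    spatial_coherence(w0, ws)$pi
  }, numeric(length(obs$timescales)))      # S x count
  obs$surrogate_quantiles <- t(apply(sp, 1, stats::quantile, probs = quantiles))
  colnames(obs$surrogate_quantiles) <- paste0("q", quantiles)
  obs$band_pvalues <- lapply(bands, function(b) {
    j <- band_indices(obs$timescales, b)
    band_pvalue(mean(obs$pi[j]), colMeans(sp[j, , drop = FALSE]))
  })
  obs
}
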