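wrap_phase <- function(x) {
  out <- x - 2 * pi * floor(x / (2 * pi) + 0.5)   # (-pi, pi] up to boundary
  out[out <= -pi] <- out[out <= -pi] + 2 * pi
  out
}

# re-transform a panel on the same grid / normalization as an existing set
retransform <- function(panel, like) {
  s <- length(like$timescales)
  panel_transform(
    panel, like$normalization,
    sigma_min = like$timescales[1],
    sigma_max = like$timescales[s] * (1 + 1e-9),
    spacing = like$timescales[2] / like$timescales[1],
    f0 = like$f0
  )
}

# per-timescale coherence between a transform set and a fitted complex
# surface (N x T x S)
surface_coherence <- function(w0, h) {
  s <- length(w0$timescales)
  vapply(seq_len(s), function(j) {
    inc <- included_times(w0$coi, j)
    a <- w0$coefficients[, inc, j]
    b <- h[, inc, j]
    den <- sqrt(mean(Mod(a)^2) * mean(Mod(b)^2))
    if (den == 0) return(0)
    Mod(mean(a * Conj(b))) / den
  }, numeric(1))
}

#' Fit a multivariate wavelet linear model
#'
#' Models the response's power-normalized transforms as a complex linear
#' combination of the predictors' transforms, timescale by timescale:
#' `w0(n, t, sigma) ~ beta_1(sigma) w1(n, t, sigma) + ... +
#' beta_K(sigma) wK(n, t, sigma)`. At each timescale the complex
#' coefficients solve the least-squares problem over stacked
#' location-time cells (outside the cone of influence), via normal
#' equations with a ridge jitter of 1e-10 on the Gram diagonal; this also
#' maximizes the spatial coherence between the response and the fitted
#' combination. The complex coefficients capture both the strength
#' (magnitude) and the phase lag (argument) of each driver's association
#' at each timescale.
#'
#' @param response Power-normalized `"normalized_set"` of the response.
#' @param predictors List of power-normalized `"normalized_set"` objects
#'   (K >= 1), optionally named.
#' @param band Timescale band `(lo, hi]` in years on which band-level
#'   statistics of this model are aggregated.
#' @return Object of class `"wavelet_model"`: `betas` (complex `K x S`),
#'   `fitted` (complex `N x T x S`), `model_coherence` (length `S`,
#'   coherence of response with fitted surface), `response`,
#'   `predictors`, `predictor_ids`, `band`, `timescales`, `coi`.
#' @export
fit_wlm <- function(response, predictors, band = NULL) {
  if (!inherits(response, "normalized_set") ||
      response$normalization != "power") {
    stop("response must be a power-normalized transform set")
  }
  if (!is.list(predictors) || length(predictors) < 1) {
    stop("need at least one predictor")
  }
  k <- length(predictors)
  ids <- names(predictors)
  if (is.null(ids) || any(ids == "")) ids <- paste0("pred", seq_len(k))
  for (p in predictors) {
    if (!inherits(p, "normalized_set") || p$normalization != "power") {
      stop("all predictors must be power-normalized transform sets")
    }
    check_compatible(response, p)
  }
  dims <- dim(response$coefficients)
  s <- length(response$timescales)
  if (is.null(band)) band <- c(response$timescales[1], response$timescales[s])
  betas <- matrix(0 + 0i, k, s, dimnames = list(ids, NULL))
  fitted <- array(0 + 0i, dim = dims)
  for (j in seq_len(s)) {
    inc <- included_times(response$coi, j)
    y <- as.vector(response$coefficients[, inc, j])
    x <- vapply(predictors, function(p) as.vector(p$coefficients[, inc, j]),
                complex(length(y)))
    x <- matrix(x, ncol = k)
    g <- Conj(t(x)) %*% x
    diag(g) <- diag(g) + 1e-10
    sv <- svd(g, nu = 0, nv = 0)$d
    if (max(sv) / min(sv) > 1e10) {
      stop(sprintf(
        "rank-deficient predictor set at timescale %.2f (collinear among: %s)",
        response$timescales[j], paste(ids, collapse = ", ")
      ))
    }
    b <- solve(g, Conj(t(x)) %*% y)
    betas[, j] <- b
    for (kk in seq_len(k)) {
      fitted[, , j] <- fitted[, , j] + b[kk] * predictors[[kk]]$coefficients[, , j]
    }
  }
  structure(
    list(
      betas = betas, fitted = fitted,
      model_coherence = surface_coherence(response, fitted),
      response = response, predictors = predictors, predictor_ids = ids,
      band = band, timescales = response$timescales, coi = response$coi
    ),
    class = "wavelet_model"
  )
}

#' @export
print.wavelet_model <- function(x, ...) {
  j <- band_indices(x$timescales, x$band)
  cat(sprintf(
    "<wavelet_model> %d predictor(s): %s\n  band (%.3g, %.3g] yr; band-mean coherence %.3f\n",
    length(x$predictor_ids), paste(x$predictor_ids, collapse = ", "),
    x$band[1], x$band[2], mean(x$model_coherence[j])
  ))
  invisible(x)
}

#' Coefficient table of a wavelet model
#'
#' @param x A `"wavelet_model"`.
#' @param ... Unused.
#' @return Data frame with one row per predictor-timescale pair:
#'   `predictor`, `timescale`, `beta_mod` (coefficient magnitude),
#'   `beta_phase` (radians), `model_coherence`.
#' @export
tidy.wavelet_model <- function(x, ...) {
  k <- nrow(x$betas)
  s <- ncol(x$betas)
  data.frame(
    predictor = rep(x$predictor_ids, times = s),
    timescale = rep(x$timescales, each = k),
    beta_mod = as.vector(Mod(x$betas)),
    beta_phase = as.vector(Arg(x$betas)),
    model_coherence = rep(x$model_coherence, each = k)
  )
}

#' One-line summary of a wavelet model
#'
#' @param x A `"wavelet_model"`.
#' @param ... Unused.
#' @return One-row data frame: number of predictors, band bounds,
#'   band-mean model coherence.
#' @export
glance.wavelet_model <- function(x, ...) {
  j <- band_indices(x$timescales, x$band)
  data.frame(
    n_predictors = length(x$predictor_ids),
    band_lo = x$band[1], band_hi = x$band[2],
    band_coherence = mean(x$model_coherence[j])
  )
}

band_model_coherence <- function(model, band) {
  mean(model$model_coherence[band_indices(model$timescales, band)])
}

#' Surrogate test for dropping one predictor
#'
#' Tests whether predictor `k` contributes significantly to the model:
#' the statistic is the band-mean coherence between the response and the
#' fitted model; null draws replace predictor `k`'s time-domain series by
#' synchrony-preserving Fourier surrogates (which retain the predictor's
#' own synchrony and spectra but break its relationship with the response
#' and the other predictors), re-transform, refit the full model and
#' recompute the statistic. The p-value uses the +1 rank rule.
#'
#' @param model A `"wavelet_model"`.
#' @param k Predictor index to test.
#' @param count Number of surrogates (>= 100; default 1000).
#' @param seed Integer seed.
#' @param band Timescale band (defaults to the model's band).
#' @return The p-value.
#' @export
drop_predictor_test <- function(model, k, count = 1000, seed = 1,
                                band = NULL) {
  if (!inherits(model, "wavelet_model")) stop("expected a `wavelet_model`")
  if (k < 1 || k > length(model$predictors)) stop("predictor index out of range")
  if (is.null(band)) band <- model$band
  obs <- band_model_coherence(model, band)
  surr <- fourier_surrogates(model$predictors[[k]]$series, count,
                             "fourier_synchrony_preserving", seed)
  stats_null <- vapply(surr, function(p) {
    preds <- model$predictors
    preds[[k]] <- retransform(p, preds[[k]])
    band_model_coherence(fit_wlm(model$response, preds, band), band)
  }, numeric(1))
  band_pvalue(obs, stats_null)
}

#' Leave-one-location-out cross-validation score
#'
#' For each location, the model is refitted on the other `N - 1`
#' locations and scored on the held-out location's cells in the band:
#' `score_n = 1 - sum|w0_n - sum_k beta_k wk_n|^2 / sum|w0_n|^2`, summing
#' over held-out time-timescale cells. Returns the mean over locations; 1
#' indicates perfect out-of-sample prediction, values near or below 0
#' indicate no out-of-sample signal. The leave-one-out unit is the
#' location, the exchangeable replicate of the stacked fit.
#'
#' @inheritParams fit_wlm
#' @param band Timescale band over which the score is accumulated.
#' @return Mean score over locations (a single number).
#' @export
loo_cv_score <- function(response, predictors, band) {
  n <- dim(response$coefficients)[1]
  if (n < 3) stop("leave-one-out needs at least 3 locations")
  jband <- band_indices(response$timescales, band)
  k <- length(predictors)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    num <- den <- 0
    for (j in jband) {
      inc <- included_times(response$coi, j)
      y <- as.vector(response$coefficients[-i, inc, j])
      x <- vapply(predictors, function(p) as.vector(p$coefficients[-i, inc, j]),
                  complex(length(y)))
      x <- matrix(x, ncol = k)
      g <- Conj(t(x)) %*% x
      diag(g) <- diag(g) + 1e-10
      b <- solve(g, Conj(t(x)) %*% y)
      y_i <- response$coefficients[i, inc, j]
      h_i <- rep(0 + 0i, length(y_i))
      for (kk in seq_len(k)) {
        h_i <- h_i + b[kk] * predictors[[kk]]$coefficients[i, inc, j]
      }
      num <- num + sum(Mod(y_i - h_i)^2)
      den <- den + sum(Mod(y_i)^2)
    }
    scores[i] <- 1 - num / den
  }
  mean(scores)
}

#' Enumerative model selection with drop tests and cross-validation
#'
#' Enumerates all predictor subsets of size 1 to `max_k`; a subset is
#' retained only if every predictor in it survives its
#' [drop_predictor_test()] at level `alpha`; retained subsets are ranked
#' by [loo_cv_score()]. Subsets scoring at least 90% of the top score are
#' flagged as competitive.
#'
#' @param response Power-normalized `"normalized_set"` of the response.
#' @param candidates Named list of candidate predictor
#'   `"normalized_set"`s.
#' @param band Timescale band.
#' @param max_k Largest subset size considered (<= 5).
#' @param alpha Drop-test significance level (default 0.05).
#' @param count Surrogates per drop test (default 1000).
#' @param seed Integer seed.
#' @return Object of class `"model_selection"`: `table` (one row per
#'   retained subset: predictors, `loo_score`, `within_90`), `models`
#'   (the fitted `"wavelet_model"`s, same order), `rejected` (subsets
#'   failing a drop test, with their worst p). Retained list may be
#'   empty.
#' @export
select_models <- function(response, candidates, band, max_k = 3,
                          alpha = 0.05, count = 1000, seed = 1) {
  if (length(candidates) < 1) stop("need at least one candidate predictor")
  if (max_k > 5) stop("`max_k` capped at 5")
  ids <- names(candidates)
  if (is.null(ids)) ids <- paste0("pred", seq_along(candidates))
  names(candidates) <- ids
  kept_models <- list()
  kept_label <- character(0)
  kept_score <- numeric(0)
  rejected <- data.frame(predictors = character(0), worst_p = numeric(0))
  for (sz in seq_len(min(max_k, length(candidates)))) {
    subsets <- utils::combn(length(candidates), sz, simplify = FALSE)
    for (sub in subsets) {
      preds <- candidates[sub]
      model <- tryCatch(fit_wlm(response, preds, band), error = function(e) NULL)
      if (is.null(model)) next
      ps <- vapply(seq_len(sz), function(kk) {
        drop_predictor_test(model, kk, count, seed + kk, band)
      }, numeric(1))
      label <- paste(ids[sub], collapse = "+")
      if (all(ps <= alpha)) {
        kept_models[[length(kept_models) + 1]] <- model
        kept_label <- c(kept_label, label)
        kept_score <- c(kept_score, loo_cv_score(response, preds, band))
      } else {
        rejected <- rbind(rejected,
                          data.frame(predictors = label, worst_p = max(ps)))
      }
    }
  }
  if (length(kept_models) == 0) {
    message("no predictor subset passed all drop tests")
    tab <- data.frame(predictors = character(0), loo_score = numeric(0),
                      within_90 = logical(0))
  } else {
    ord <- order(kept_score, decreasing = TRUE)
    kept_models <- kept_models[ord]
    tab <- data.frame(
      predictors = kept_label[ord],
      loo_score = kept_score[ord],
      within_90 = kept_score[ord] >= 0.9 * max(kept_score)
    )
  }
  structure(
    list(table = tab, models = kept_models, rejected = rejected,
         alpha = alpha, band = band),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> band (%.3g, %.3g], alpha = %g\n",
              x$band[1], x$band[2], x$alpha))
  if (nrow(x$table) == 0) cat("  no subset retained\n") else print(x$table)
  invisible(x)
}

#' @export
tidy.model_selection <- function(x, ...) x$table

#' Coefficient-phase diagnostic
#'
#' Compares two estimates of the phase lag between the response and
#' predictor `k` at each timescale: the phase `theta` of the mean unit
#' phasor of `eta(n, t) = Arg(w0 * Conj(wk))` (the empirical per-cell
#' phase difference), and the phase of the fitted coefficient
#' `beta_k(sigma)`. For a genuine consistent association the two should
#' agree; the wrapped discrepancy is returned.
#'
#' @param model A `"wavelet_model"`.
#' @param k Predictor index.
#' @return Object of class `"phase_diagnostic"`: data frame with
#'   `timescale`, `eta_mean_phase`, `beta_phase`, `discrepancy` (wrapped
#'   to `(-pi, pi]`).
#' @export
phase_diagnostic <- function(model, k) {
  if (k < 1 || k > length(model$predictors)) stop("predictor index out of range")
  s <- length(model$timescales)
  w0 <- model$response$coefficients
  wk <- model$predictors[[k]]$coefficients
  theta <- vapply(seq_len(s), function(j) {
    inc <- included_times(model$coi, j)
    eta <- Arg(w0[, inc, j] * Conj(wk[, inc, j]))
    Arg(mean(exp(1i * eta)))
  }, numeric(1))
  bp <- Arg(model$betas[k, ])
  out <- data.frame(
    timescale = model$timescales,
    eta_mean_phase = theta,
    beta_phase = bp,
    discrepancy = wrap_phase(theta - bp)
  )
  class(out) <- c("phase_diagnostic", "data.frame")
  out
}

#' Spatial permutation test for local association
#'
#' Tests whether the association between response and predictor is
#' location-specific ("local") rather than an average association that
#' survives arbitrary re-pairing of locations. The statistic is the
#' band-mean spatial coherence with matched locations; null draws permute
#' the predictor's location labels relative to the response. A small
#' p-value indicates local associations, as expected for a Moran driver
#' acting in place rather than dispersal-style mixing.
#'
#' @param response,predictor Power-normalized `"normalized_set"`s.
#' @param band Timescale band.
#' @param n_perm Number of permutations (>= 100; default 999).
#' @param seed Integer seed.
#' @return The p-value (+1 rank rule).
#' @export
spatial_shuffle_test <- function(response, predictor, band, n_perm = 999,
                                 seed = 1) {
  check_compatible(response, predictor)
  n <- dim(response$coefficients)[1]
  if (n < 3) stop("need at least 3 locations")
  if (n_perm < 100) stop("need at least 100 permutations")
  jband <- band_indices(response$timescales, band)
  band_coh <- function(pred_coef) {
    mean(vapply(jband, function(j) {
      inc <- included_times(response$coi, j)
      a <- response$coefficients[, inc, j]
      b <- pred_coef[, inc, j]
      Mod(mean(a * Conj(b))) / sqrt(mean(Mod(a)^2) * mean(Mod(b)^2))
    }, numeric(1)))
  }
  obs <- band_coh(predictor$coefficients)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(r) {
    band_coh(predictor$coefficients[sample(n), , , drop = FALSE])
  }, numeric(1))
  band_pvalue(obs, null_stats)
}
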