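#' Mean field of a fitted wavelet model
#'
#' The across-location average of the fitted surface,
#' `r_h(t, sigma) = (1/N) sum_n h_n(t, sigma)`. By linearity it equals
#' `sum_k beta_k(sigma) r_k(t, sigma)` where `r_k` is the wavelet mean
#' field of predictor `k`; both routes are computed and must agree to
#' 1e-10 (an internal consistency check).
#'
#' @param model A `"wavelet_model"`.
#' @return A `"mean_field"` of kind `"wmf"` (the model mean field).
#' @export
model_mean_field <- function(model) {
  if (!inherits(model, "wavelet_model")) stop("expected a `wavelet_model`")
  direct <- apply(model$fitted, c(2, 3), mean)
  via_predictors <- matrix(0 + 0i, nrow(direct), ncol(direct))
  for (k in seq_along(model$predictors)) {
    rk <- apply(model$predictors[[k]]$coefficients, c(2, 3), mean)
    via_predictors <- via_predictors +
      sweep(rk, 2, model$betas[k, ], "*")
  }
  if (max(Mod(direct - via_predictors)) > 1e-10 * max(1, max(Mod(direct)))) {
    stop("internal error: model mean-field identity violated")
  }
  new_mean_field(direct, "wmf", model$timescales, model$coi)
}

#' Predicted synchrony surface under the wavelet Moran theorem
#'
#' The synchrony the response would show if the modeled drivers were its
#' only synchronizing influences: the surface
#' `|Pi(sigma)| * |r_h(t, sigma)|`, the model mean-field magnitude scaled
#' by the model-response coherence at each timescale. Observed synchrony
#' is expected to be at least this large, the excess reflecting
#' synchronizing influences absent from the model.
#'
#' @param model A `"wavelet_model"`.
#' @return A `"mean_field"`-like object of kind `"predicted"` whose
#'   `values` are real (magnitudes).
#' @export
predicted_synchrony <- function(model) {
  mf <- model_mean_field(model)
  vals <- sweep(Mod(mf$values), 2, model$model_coherence, "*")
  new_mean_field(vals, "predicted", model$timescales, model$coi)
}

#' Fraction of band synchrony explained by a wavelet model
#'
#' The wavelet Moran theorem states that, when the modeled drivers are
#' the only synchronizers, the observed mean squared synchrony at
#' timescale `sigma` approximately equals the model's mean squared
#' synchrony times the squared model-response coherence:
#' `msq_0(sigma) ~ |Pi(sigma)|^2 * msq_h(sigma)`. Aggregating both sides
#' over the grid timescales of a band (equal weight per grid point)
#' yields the fraction of observed band synchrony the model explains:
#' `sum |Pi|^2 msq_h / sum msq_0`.
#'
#' @param model A `"wavelet_model"`.
#' @param band Timescale band (defaults to the model's band).
#' @return The explained fraction (a single nonnegative number; 1 when
#'   the response exactly equals the fitted model).
#' @export
fraction_explained <- function(model, band = NULL) {
  if (is.null(band)) band <- model$band
  j <- band_indices(model$timescales, band)
  msq_obs <- wmf(model$response)$msq
  if (sum(msq_obs[j]) == 0) stop("observed synchrony is zero in the band")
  msq_h <- model_mean_field(model)$msq
  sum(model$model_coherence[j]^2 * msq_h[j]) / sum(msq_obs[j])
}

#' Partition explained synchrony into drivers and interactions
#'
#' The synchrony attribution theorem decomposes the model mean field's
#' squared magnitude using `r_h = sum_k beta_k r_k`:
#' `msq_h(sigma) = sum_k |beta_k|^2 msq_k(sigma) +
#' sum_{j<k} 2 Re[beta_j Conj(beta_k) C_jk(sigma)]`,
#' where `C_jk` is the time-mean of `r_j * Conj(r_k)` (over the same
#' cells as `msq`). Scaling each band-aggregated term by the same
#' machinery as [fraction_explained()] partitions the explained fraction
#' of observed synchrony into per-driver components and an interaction
#' component (the cross terms, positive when drivers' mean fields
#' reinforce and negative when they counteract). Components sum exactly
#' to the total explained fraction.
#'
#' @param model A `"wavelet_model"`.
#' @param band Timescale band (defaults to the model's band).
#' @return Object of class `"synchrony_partition"`: `band`,
#'   `fraction_total`, `fraction_per_predictor` (named numeric),
#'   `fraction_interactions`, `pairwise_terms` (named numeric, one per
#'   unordered predictor pair).
#' @export
attribute_synchrony <- function(model, band = NULL) {
  if (!inherits(model, "wavelet_model")) stop("expected a `wavelet_model`")
  if (is.null(band)) band <- model$band
  j <- band_indices(model$timescales, band)
  k <- length(model$predictors)
  ids <- model$predictor_ids
  msq_obs <- wmf(model$response)$msq
  denom <- sum(msq_obs[j])
  if (denom == 0) stop("observed synchrony is zero in the band")
  pi2 <- model$model_coherence^2
  rk <- lapply(model$predictors, function(p) apply(p$coefficients, c(2, 3), mean))
  # per-timescale msq of each predictor mean field, and cross terms
  time_mean <- function(mat_col, jj) {
    inc <- included_times(model$coi, jj)
    mean(mat_col[inc])
  }
  per_pred <- stats::setNames(numeric(k), ids)
  for (kk in seq_len(k)) {
    msq_k <- vapply(j, function(jj) time_mean(Mod(rk[[kk]][, jj])^2, jj),
                    numeric(1))
    per_pred[kk] <- sum(pi2[j] * Mod(model$betas[kk, j])^2 * msq_k) / denom
  }
  pairwise <- numeric(0)
  if (k >= 2) {
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        cross <- vapply(j, function(jj) {
          cj <- time_mean(rk[[a]][, jj] * Conj(rk[[b]][, jj]), jj)
          2 * Re(model$betas[a, jj] * Conj(model$betas[b, jj]) * cj)
        }, numeric(1))
        pairwise[paste(ids[a], ids[b], sep = ":")] <- sum(pi2[j] * cross) / denom
      }
    }
  }
  structure(
    list(
      band = band,
      fraction_total = sum(per_pred) + sum(pairwise),
      fraction_per_predictor = per_pred,
      fraction_interactions = sum(pairwise),
      pairwise_terms = pairwise
    ),
    class = "synchrony_partition"
  )
}

#' @export
print.synchrony_partition <- function(x, ...) {
  cat(sprintf("<synchrony_partition> band (%.3g, %.3g]\n", x$band[1], x$band[2]))
  cat(sprintf("  total explained fraction: %.4f\n", x$fraction_total))
  for (nm in names(x$fraction_per_predictor)) {
    cat(sprintf("  %s: %.4f\n", nm, x$fraction_per_predictor[[nm]]))
  }
  cat(sprintf("  interactions: %.4f\n", x$fraction_interactions))
  invisible(x)
}

#' Partition in long (tidy) form
#'
#' @param x A `"synchrony_partition"`.
#' @param ... Unused.
#' @return Data frame with columns `component`, `fraction`.
#' @export
tidy.synchrony_partition <- function(x, ...) {
  data.frame(
    component = c(names(x$fraction_per_predictor), "interactions", "total"),
    fraction = c(unname(x$fraction_per_predictor), x$fraction_interactions,
                 x$fraction_total)
  )
}

#' Interaction randomization of one predictor
#'
#' Quantifies how much of the model's synchrony depends on the alignment
#' between predictor `k` and the other drivers. Each draw replaces
#' predictor `k`'s time-domain series with a Fourier surrogate,
#' re-transforms it, and rebuilds the model mean field *with the original
#' fitted coefficients*; the per-timescale mean squared model synchrony
#' is recorded. `mode = "synchrony_preserving"` (shared phase draw)
#' preserves predictor `k`'s own synchrony but breaks its relationship
#' with the other drivers, isolating the interaction contribution;
#' `mode = "asynchronous"` (independent phase draws) additionally
#' destroys `k`'s own synchrony. The one-sided rank p compares the
#' observed band-mean against the synchrony-preserving null.
#'
#' Retaining the fitted coefficients (rather than refitting per
#' surrogate) isolates the between-driver alignment effect; setting
#' `zero_beta = TRUE` instead zeroes predictor `k`'s coefficient and
#' returns the resulting deterministic curve (no surrogates).
#'
#' @param model A `"wavelet_model"`.
#' @param k Predictor index to randomize.
#' @param count Number of surrogates per mode (>= 100; default 1000).
#' @param band Timescale band (defaults to the model's band).
#' @param seed Integer seed.
#' @param mode `"synchrony_preserving"`, `"asynchronous"`, or `"both"`.
#' @param zero_beta If TRUE, return the curve with `beta_k = 0` instead
#'   of randomizing.
#' @return Object of class `"interaction_randomization"`: `timescales`
#'   (band grid), `observed` (per-timescale msq of the model mean
#'   field), per-mode surrogate mean curves, `band_observed`,
#'   `band_surrogate_mean`, and `p` (vs the synchrony-preserving null);
#'   or, with `zero_beta`, the observed and zeroed curves.
#' @export
interaction_randomization <- function(model, k, count = 1000, band = NULL,
                                      seed = 1,
                                      mode = c("both", "synchrony_preserving",
                                               "asynchronous"),
                                      zero_beta = FALSE) {
  if (!inherits(model, "wavelet_model")) stop("expected a `wavelet_model`")
  if (k < 1 || k > length(model$predictors)) stop("predictor index out of range")
  mode <- match.arg(mode)
  if (is.null(band)) band <- model$band
  j <- band_indices(model$timescales, band)
  rk <- lapply(model$predictors, function(p) apply(p$coefficients, c(2, 3), mean))
  mf_from <- function(rk_list) {
    r <- matrix(0 + 0i, nrow(rk_list[[1]]), ncol(rk_list[[1]]))
    for (kk in seq_along(rk_list)) {
      r <- r + sweep(rk_list[[kk]], 2, model$betas[kk, ], "*")
    }
    new_mean_field(r, "wmf", model$timescales, model$coi)$msq
  }
  observed <- mf_from(rk)
  if (zero_beta) {
    rk0 <- rk
    rk0[[k]] <- rk0[[k]] * 0
    zb <- mf_from(rk0)
    return(structure(
      list(timescales = model$timescales[j], observed = observed[j],
           zero_beta = zb[j], band = band),
      class = "interaction_randomization"
    ))
  }
  run_mode <- function(kind, seed_off) {
    surr <- fourier_surrogates(model$predictors[[k]]$series, count, kind,
                               seed + seed_off)
    vapply(surr, function(p) {
      rks <- rk
      rks[[k]] <- apply(retransform(p, model$predictors[[k]])$coefficients,
                        c(2, 3), mean)
      mf_from(rks)
    }, numeric(length(observed)))          # S x count
  }
  out <- list(timescales = model$timescales[j], observed = observed[j],
              band = band, band_observed = mean(observed[j]))
  if (mode %in% c("both", "synchrony_preserving")) {
    sp <- run_mode("fourier_synchrony_preserving", 0)
    out$sync_preserving_mean <- rowMeans(sp)[j]
    band_stats <- colMeans(sp[j, , drop = FALSE])
    out$band_surrogate_mean <- mean(band_stats)
    out$p <- band_pvalue(out$band_observed, band_stats)
  }
  if (mode %in% c("both", "asynchronous")) {
    as_ <- run_mode("fourier_independent", 1)
    out$asynchronous_mean <- rowMeans(as_)[j]
    out$band_asynchronous_mean <- mean(colMeans(as_[j, , drop = FALSE]))
  }
  structure(out, class = "interaction_randomization")
}

#' @export
print.interaction_randomization <- function(x, ...) {
  cat(sprintf("<interaction_randomization> band (%.3g, %.3g]\n",
              x$band[1], x$band[2]))
  cat(sprintf("  observed band msq: %.4f\n", mean(x$observed)))
  if (!is.null(x$band_surrogate_mean)) {
    cat(sprintf("  synchrony-preserving surrogate mean: %.4f (p = %.4g)\n",
                x$band_surrogate_mean, x$p))
  }
  if (!is.null(x$band_asynchronous_mean)) {
    cat(sprintf("  asynchronous surrogate mean: %.4f\n",
                x$band_asynchronous_mean))
  }
  if (!is.null(x$zero_beta)) {
    cat(sprintf("  beta_k = 0 band msq: %.4f\n", mean(x$zero_beta)))
  }
  invisible(x)
}
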