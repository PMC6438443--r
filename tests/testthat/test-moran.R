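fig1_model <- function(phi = 0, seed = 1, spacing = 1.1, band = c(16, 25)) {
  sc <- generate_fig1(phi, seed)
  resp <- panel_transform(sc$gamma3, spacing = spacing)
  preds <- list(alpha = panel_transform(sc$alpha, spacing = spacing),
                beta_lag = panel_transform(sc$beta_lagged, spacing = spacing))
  fit_wlm(resp, preds, band = band)
}

test_that("the model mean field agrees between its two computation routes", {
  m <- fig1_model(seed = 101)
  # model_mean_field() errors if the direct and per-predictor routes differ
  mf <- model_mean_field(m)
  expect_s3_class(mf, "mean_field")
  direct <- apply(m$fitted, c(2, 3), mean)
  expect_lt(max(Mod(mf$values - direct)), 1e-12)
})

test_that("single-predictor edge cases of the model mean field", {
  ex <- make_exact_model(1 + 0i, seed = 102)
  m <- fit_wlm(ex$response, ex$predictors)
  mf <- model_mean_field(m)
  pred_mf <- wmf(ex$predictors[[1]])
  expect_lt(max(Mod(mf$values - pred_mf$values)), 1e-8)
  # beta == 0: response orthogonal in expectation, but force exactly:
  m0 <- m
  m0$betas[] <- 0
  m0$fitted[] <- 0
  expect_lt(max(Mod(model_mean_field(m0)$values)), 1e-12)
})

test_that("predicted synchrony equals model synchrony when the fit is exact, else shrinks", {
  ex <- make_exact_model(0.7 * exp(1i * 0.4), seed = 103)
  m <- fit_wlm(ex$response, ex$predictors)
  ps <- predicted_synchrony(m)
  mf <- model_mean_field(m)
  expect_lt(max(abs(Mod(ps$values) - Mod(mf$values))), 1e-8)
  # unrelated response: coherence ~ 0, predicted synchrony ~ 0
  vals <- vapply(1:5, function(s) {
    preds <- list(x = quick_transform(noise_panel(12, 60, seed = 500 + s)))
    resp <- quick_transform(noise_panel(12, 60, seed = 600 + s))
    m2 <- fit_wlm(resp, preds, band = c(6, 20))
    mean_squared_synchrony(predicted_synchrony(m2), c(6, 20))
  }, numeric(1))
  expect_lt(mean(vals), 0.1)
})

test_that("observed band synchrony exceeds model-predicted synchrony for driven populations", {
  wins <- vapply(1:10, function(s) {
    m <- fig1_model(seed = 110 + s)
    obs <- mean_squared_synchrony(wmf(m$response), c(16, 25))
    pred <- mean_squared_synchrony(predicted_synchrony(m), c(16, 25))
    pred <= obs
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("fraction explained is 1 for a noise-free construction and small for noise", {
  ex <- make_exact_model(c(0.6 + 0i, 0.3 * exp(1i * 1)), seed = 120)
  m <- fit_wlm(ex$response, ex$predictors, band = c(6, 20))
  expect_lt(abs(fraction_explained(m) - 1), 1e-8)
  noise_fracs <- vapply(1:5, function(s) {
    resp <- quick_transform(noise_panel(6, 48, seed = 130 + s))
    preds <- list(x = quick_transform(noise_panel(6, 48, seed = 140 + s)))
    fraction_explained(fit_wlm(resp, preds, band = c(6, 20)))
  }, numeric(1))
  expect_lt(mean(noise_fracs), 0.1)
})

test_that("two drivers explain more band synchrony than one when both act", {
  wins <- vapply(1:10, function(s) {
    sc <- generate_fig1(0, seed = 150 + s)
    resp <- panel_transform(sc$gamma3, spacing = 1.1)
    both <- fit_wlm(resp, list(
      alpha = panel_transform(sc$alpha, spacing = 1.1),
      beta_lag = panel_transform(sc$beta_lagged, spacing = 1.1)
    ), band = c(10, 30))
    alone <- fit_wlm(resp, list(
      alpha = panel_transform(sc$alpha, spacing = 1.1)
    ), band = c(10, 30))
    fraction_explained(both) > fraction_explained(alone)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("attribution components sum to the total and respect edge cases", {
  m <- fig1_model(seed = 160)
  part <- attribute_synchrony(m)
  expect_lt(abs(part$fraction_total -
                  (sum(part$fraction_per_predictor) +
                     part$fraction_interactions)), 1e-8)
  expect_lt(abs(part$fraction_total - fraction_explained(m)), 1e-8)
  expect_gte(part$fraction_total, 0)
  # K = 1: no interactions
  ex <- make_exact_model(0.9 + 0i, seed = 161)
  m1 <- fit_wlm(ex$response, ex$predictors, band = c(6, 20))
  p1 <- attribute_synchrony(m1)
  expect_equal(p1$fraction_interactions, 0)
  expect_equal(unname(p1$fraction_per_predictor[1]), p1$fraction_total)
})

test_that("orthogonal predictor mean fields produce a vanishing interaction term", {
  # build two predictors whose mean fields are exactly orthogonal in time:
  # locations share cos / sin carriers a quarter period apart
  tt <- 48
  t0 <- 0:(tt - 1)
  p1 <- st_panel(rbind(cos(2 * pi * t0 / 12), cos(2 * pi * t0 / 12)))
  p2 <- st_panel(rbind(sin(2 * pi * t0 / 12), sin(2 * pi * t0 / 12)))
  w1 <- quick_transform(p1)
  w2 <- quick_transform(p2)
  resp <- w1
  resp$coefficients <- w1$coefficients + w2$coefficients
  m <- fit_wlm(resp, list(a = w1, b = w2), band = c(10, 14))
  part <- attribute_synchrony(m)
  # cross term is the time-mean of r1 conj(r2): quarter-cycle carriers make
  # the real part average to ~0 over full cycles relative to the direct terms
  expect_lt(abs(part$fraction_interactions),
            0.05 * max(part$fraction_per_predictor))
})

test_that("interactions flip from reinforcing to counteracting as phi crosses 0.5", {
  inter <- function(phi, seed) {
    attribute_synchrony(fig1_model(phi, seed))$fraction_interactions
  }
  pos <- vapply(1:8, function(s) inter(0, 170 + s), numeric(1))
  neg <- vapply(1:8, function(s) inter(1, 180 + s), numeric(1))
  expect_gte(mean(pos > 0), 0.9)
  expect_gte(mean(neg < 0), 0.9)
})

test_that("interaction randomization: a zero-coefficient predictor changes nothing", {
  ex <- make_exact_model(c(0.8 + 0i, 0 + 0i), seed = 190)
  m <- fit_wlm(ex$response, ex$predictors, band = c(6, 20))
  m$betas[2, ] <- 0 # exactly zero contribution of predictor 2
  res <- interaction_randomization(m, 2, count = 100, seed = 191,
                                   mode = "synchrony_preserving")
  expect_lt(max(abs(res$sync_preserving_mean - res$observed)), 1e-10)
  res0 <- interaction_randomization(m, 2, zero_beta = TRUE)
  expect_lt(max(abs(res0$zero_beta - res0$observed)), 1e-12)
})

test_that("randomizing away driver alignment lowers model synchrony at phi = 0", {
  wins <- vapply(1:5, function(s) {
    m <- fig1_model(seed = 200 + s)
    res <- interaction_randomization(m, 1, count = 100, seed = 300 + s,
                                     mode = "both")
    c(res$band_surrogate_mean < res$band_observed,
      res$band_asynchronous_mean <= res$band_surrogate_mean + 1e-12)
  }, logical(2))
  expect_gte(mean(wins[1, ]), 0.9) # interactions removed -> less synchrony
  expect_gte(mean(wins[2, ]), 0.6) # breaking own synchrony lowers it further
})
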