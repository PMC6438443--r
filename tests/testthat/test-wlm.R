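test_that("an exactly linear response recovers its complex coefficients at every timescale", {
  ex <- make_exact_model(c(0.5 * exp(1i * pi / 3), 1.2 * exp(-1i * 0.8)))
  m <- fit_wlm(ex$response, ex$predictors)
  expect_lt(max(Mod(m$betas[1, ] - 0.5 * exp(1i * pi / 3))), 1e-8)
  expect_lt(max(Mod(m$betas[2, ] - 1.2 * exp(-1i * 0.8))), 1e-8)
  expect_lt(max(abs(m$model_coherence - 1)), 1e-8)
  # fitted surface reproduces betas applied to predictor transforms
  rebuilt <- m$betas[1, 1] * ex$predictors[[1]]$coefficients[, , 1] +
    m$betas[2, 1] * ex$predictors[[2]]$coefficients[, , 1]
  expect_lt(max(Mod(m$fitted[, , 1] - rebuilt)), 1e-10)
})

test_that("duplicated predictors are reported as collinear", {
  w <- quick_transform(noise_panel(4, 40, seed = 52))
  expect_error(fit_wlm(w, list(a = w, b = w)), "collinear")
})

test_that("fitted coherence dominates any single predictor's coherence (optimality)", {
  set.seed(53)
  sc <- generate_fig1(0, seed = 53)
  resp <- panel_transform(sc$gamma3, spacing = 1.1)
  preds <- list(alpha = panel_transform(sc$alpha, spacing = 1.1),
                beta_lag = panel_transform(sc$beta_lagged, spacing = 1.1))
  m <- fit_wlm(resp, preds, band = c(16, 25))
  for (p in preds) {
    single <- spatial_coherence(resp, p)$pi
    expect_true(all(m$model_coherence >= single - 1e-8))
  }
})

test_that("the two-driver construction yields the built-in coefficient phases", {
  sc <- generate_fig1(0, seed = 54)
  j20 <- function(m) which.min(abs(m$timescales - 20))
  # gamma1 ~ -alpha: antiphase
  m1 <- fit_wlm(panel_transform(sc$gamma1),
                list(alpha = panel_transform(sc$alpha)), band = c(16, 25))
  ph1 <- Arg(m1$betas[1, j20(m1)])
  expect_lt(abs(abs(ph1) - pi), 0.3)
  # gamma2 ~ -beta(t-5): antiphase composed with a quarter-cycle lag
  m2 <- fit_wlm(panel_transform(sc$gamma2),
                list(beta = panel_transform(sc$beta)), band = c(16, 25))
  ph2 <- Arg(m2$betas[1, j20(m2)])
  expect_lt(abs(ph2 - pi / 2), 0.3)
})

test_that("beta estimates converge to truth as noise vanishes", {
  set.seed(55)
  n <- 6
  tt <- 48
  base <- noise_panel(n, tt, seed = 56)
  wb <- quick_transform(base)
  truth <- 0.8 * exp(1i * 1.1)
  for (noise_sd in c(0.5, 0)) {
    resp <- wb
    set.seed(57)
    noise <- array(complex(real = rnorm(length(wb$coefficients)),
                           imaginary = rnorm(length(wb$coefficients))),
                   dim = dim(wb$coefficients))
    resp$coefficients <- truth * wb$coefficients + noise_sd * noise
    m <- fit_wlm(resp, list(x = wb))
    err <- max(Mod(m$betas[1, ] - truth))
    if (noise_sd == 0) expect_lt(err, 1e-6) else expect_lt(err, 1)
  }
})

test_that("refitting with permuted location order leaves betas unchanged", {
  sc <- generate_fig1(0, seed = 58)
  resp <- panel_transform(sc$gamma1, spacing = 1.1)
  pred <- panel_transform(sc$alpha, spacing = 1.1)
  m <- fit_wlm(resp, list(a = pred))
  perm <- sample(26)
  resp2 <- resp
  pred2 <- pred
  resp2$coefficients <- resp$coefficients[perm, , , drop = FALSE]
  pred2$coefficients <- pred$coefficients[perm, , , drop = FALSE]
  m2 <- fit_wlm(resp2, list(a = pred2))
  expect_lt(max(Mod(m$betas - m2$betas)), 1e-10)
})

test_that("leave-one-out scores separate true signal from pure noise predictors", {
  # response equal to a predictor: near-perfect out-of-sample score
  ex <- make_exact_model(1 + 0i)
  band <- c(4, 20)
  expect_gt(loo_cv_score(ex$response, ex$predictors, band), 1 - 1e-8)
  # independent noise response on a noise predictor: no signal
  scores <- vapply(1:8, function(s) {
    resp <- quick_transform(noise_panel(6, 48, seed = 300 + s))
    pred <- list(x = quick_transform(noise_panel(6, 48, seed = 400 + s)))
    loo_cv_score(resp, pred, band)
  }, numeric(1))
  expect_lt(mean(scores), 0.05)
})

test_that("adding a pure-noise predictor cannot inflate the cross-validated score", {
  band <- c(10, 30)
  diffs <- vapply(1:5, function(s) {
    sc <- generate_fig1(0, seed = 500 + s)
    resp <- panel_transform(sc$gamma1, spacing = 1.1)
    true_pred <- list(alpha = panel_transform(sc$alpha, spacing = 1.1))
    noise_pred <- c(true_pred,
                    list(junk = panel_transform(noise_panel(26, 60, seed = 600 + s),
                                                spacing = 1.1)))
    loo_cv_score(resp, noise_pred, band) - loo_cv_score(resp, true_pred, band)
  }, numeric(1))
  expect_lt(mean(diffs), 0.02)
})

test_that("drop tests flag true drivers and spare noise predictors", {
  sc <- generate_fig1(0, seed = 61)
  resp <- panel_transform(sc$gamma3, spacing = 1.1)
  preds <- list(alpha = panel_transform(sc$alpha, spacing = 1.1),
                junk = panel_transform(noise_panel(26, 60, seed = 62),
                                       spacing = 1.1))
  m <- fit_wlm(resp, preds, band = c(16, 25))
  p_true <- drop_predictor_test(m, 1, count = 120, seed = 63)
  p_junk <- drop_predictor_test(m, 2, count = 120, seed = 64)
  expect_lte(p_true, 0.05)
  expect_gt(p_junk, 0.05)
  expect_gte(p_true, 1 / 121)
  expect_error(drop_predictor_test(m, 5), "out of range")
})

test_that("model selection keeps the true drivers and drops noise", {
  # strong-signal panels keep the selection decisive at modest surrogate counts
  resp_panel <- generate_sync_panel(12, 60, 20, 0.6, seed = 71)
  pred_panel <- generate_sync_panel(12, 60, 20, 0.6, seed = 71) # same draw
  candidates <- list(
    true = panel_transform(pred_panel, spacing = 1.15),
    junk = panel_transform(noise_panel(12, 60, seed = 73), spacing = 1.15)
  )
  sel <- select_models(panel_transform(resp_panel, spacing = 1.15), candidates,
                       band = c(14, 28), max_k = 2, alpha = 0.05,
                       count = 110, seed = 74)
  expect_gt(nrow(sel$table), 0)
  expect_equal(sel$table$predictors[1], "true")
  expect_false("junk" %in% sel$table$predictors)
  expect_gt(sel$table$loo_score[1], 0.9)
})

test_that("all-noise candidate sets are rejected by the selection procedure", {
  resp <- quick_transform(noise_panel(8, 48, seed = 81))
  candidates <- list(
    n1 = quick_transform(noise_panel(8, 48, seed = 82)),
    n2 = quick_transform(noise_panel(8, 48, seed = 83))
  )
  expect_message(
    sel <- select_models(resp, candidates, band = c(6, 20), max_k = 2,
                         alpha = 0.05, count = 110, seed = 84),
    "no predictor subset"
  )
  expect_equal(nrow(sel$table), 0)
})

test_that("coefficient phases agree with the empirical cross-phase diagnostic", {
  # response = e^{i pi/4} predictor: both estimators give pi/4, discrepancy 0
  ex <- make_exact_model(exp(1i * pi / 4))
  m <- fit_wlm(ex$response, ex$predictors)
  d <- phase_diagnostic(m, 1)
  expect_lt(max(abs(d$eta_mean_phase - pi / 4)), 1e-6)
  expect_lt(max(abs(d$beta_phase - pi / 4)), 1e-6)
  expect_lt(max(abs(d$discrepancy)), 1e-6)
  # noisy single-driver model: the two phase estimates stay close at the
  # driven timescale
  sc <- generate_fig1(0, seed = 91)
  m1 <- fit_wlm(panel_transform(sc$gamma1),
                list(alpha = panel_transform(sc$alpha)), band = c(16, 25))
  d1 <- phase_diagnostic(m1, 1)
  j <- which.min(abs(d1$timescale - 20))
  expect_lt(abs(d1$discrepancy[j]), 0.5)
  expect_lt(abs(abs(d1$eta_mean_phase[j]) - pi), 0.3)
})

test_that("the spatial permutation test detects local association and respects bounds", {
  # matched pairing is maximal when predictor equals response
  w <- quick_transform(generate_sync_panel(10, 50, 12, 0.7, seed = 95),
                       spacing = 1.15)
  wn <- w
  set.seed(96)
  wn$coefficients <- w$coefficients +
    0.3 * array(complex(real = rnorm(length(w$coefficients)),
                        imaginary = rnorm(length(w$coefficients))),
                dim = dim(w$coefficients))
  p <- spatial_shuffle_test(wn, w, band = c(8, 20), n_perm = 199, seed = 97)
  expect_equal(p, 1 / 200)
  # a spatially constant predictor carries no locality signal
  xc <- matrix(rep(rnorm(50), each = 10), 10, 50)
  wc <- quick_transform(st_panel(xc + 1e-6 * rnorm(500)), spacing = 1.15)
  p2 <- spatial_shuffle_test(wn, wc, band = c(8, 20), n_perm = 199, seed = 98)
  expect_gt(p2, 0.05)
})
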