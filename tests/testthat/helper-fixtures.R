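# Shared fixture builders. Everything is generated in code; no stored data.

# quick power/phasor transform on a coarse grid (keeps module tests fast;
# the acceptance tests use the default fine grid)
quick_transform <- function(panel, method = "power", spacing = 1.15, ...) {
  panel_transform(panel, method, spacing = spacing, ...)
}

# small white-noise panel
noise_panel <- function(n = 5, tt = 40, seed = 1) {
  set.seed(seed)
  st_panel(matrix(rnorm(n * tt), n, tt))
}

# panel holding one deterministic series replicated with tiny independent
# jitter (keeps st_panel's N >= 2 while behaving like a single series)
sine_panel <- function(tt, period, fun = sin, n = 2) {
  t0 <- 0:(tt - 1)
  x <- matrix(rep(sqrt(2) * fun(2 * pi * t0 / period), each = n), n, tt,
              byrow = FALSE)
  st_panel(x)
}

grid_step_apart <- function(a, b, spacing = 1.05) {
  abs(log(a / b)) <= log(spacing) * 1.0001
}

# exact complex-linear response built from noise-panel transforms
make_exact_model <- function(coefs = 0.5 * exp(1i * pi / 3), seed = 51,
                             n = 6, tt = 48, spacing = 1.15) {
  set.seed(seed)
  preds <- lapply(seq_along(coefs), function(k) {
    quick_transform(noise_panel(n, tt, seed = seed + k), spacing = spacing)
  })
  names(preds) <- paste0("x", seq_along(coefs))
  resp <- preds[[1]]
  resp$coefficients <- resp$coefficients * 0
  for (k in seq_along(coefs)) {
    resp$coefficients <- resp$coefficients + coefs[k] * preds[[k]]$coefficients
  }
  list(response = resp, predictors = preds)
}

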