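#' Two-driver synthetic scenario with interacting synchronizing factors
#'
#' Generates the fully specified two-driver construction used throughout
#' the package's validation: 26 locations, 60 years (t = 0, ..., 59), a
#' 20-year periodicity (`w = 2*pi/20`), and a phase parameter `phi`
#' controlling whether the two drivers reinforce or counteract each other.
#'
#' The drivers are
#' `alpha(n,t) = sqrt(1/4) * sqrt(2) * sin(w t) + sqrt(3/4) * noise` and
#' `beta(n,t)  = sqrt(1/4) * sqrt(2) * cos(w t - phi*pi) + sqrt(3/4) * noise`,
#' so each driver's synchronous sinusoid contributes 1/4 of its variance
#' and independent standard-normal local noise the remaining 3/4 (a 1:3
#' combination ratio). Three population variables are driven by them:
#' `gamma1` by `-alpha(n,t)`, `gamma2` by `-beta(n, t-5)` (a 5-year lag,
#' one quarter of the 20-year cycle), and `gamma3` by
#' `-(alpha(n,t) + beta(n, t-5)) / f` with `f = sqrt(2 + cos(phi*pi)/2)`
#' chosen so the driving signal has unit variance through time; each
#' population combines its driving signal with fresh local noise in the
#' same 1:3 ratio. At `phi = 0` the two drivers reinforce (positive
#' interaction); the interaction changes sign as `phi` passes 0.5.
#'
#' `beta` is generated on t = -5, ..., 59 internally so the lag is
#' defined; its pre-sample synchronous part follows the formula and its
#' pre-sample local noise is freshly drawn.
#'
#' @param phi Phase offset parameter in `[0, 1]` (units of pi radians).
#' @param seed Integer seed; the same seed reproduces the scenario
#'   bitwise.
#' @param n_locations,n_years Panel dimensions (defaults 26 and 60).
#' @return Object of class `"two_driver_scenario"`: [st_panel()] elements
#'   `alpha`, `beta`, `gamma1`, `gamma2`, `gamma3`, plus `phi`, `f`,
#'   `w`, `period`, `lag` and `seed`.
#' @examples
#' sc <- generate_fig1(phi = 0, seed = 1)
#' sc$f^2  # 2.5 at phi = 0
#' @export
generate_fig1 <- function(phi, seed, n_locations = 26, n_years = 60) {
  if (length(phi) != 1 || is.na(phi) || phi < 0 || phi > 1) {
    stop("`phi` must lie in [0, 1]")
  }
  n <- n_locations
  tt <- n_years
  lag <- 5
  w <- 2 * pi / 20
  a_s <- sqrt(1 / 4)
  a_l <- sqrt(3 / 4)
  f <- sqrt(2 + 0.5 * cos(phi * pi))
  t_obs <- 0:(tt - 1)
  t_ext <- (-lag):(tt - 1)                       # beta needs 5 pre-sample years
  set.seed(seed)
  noise <- function(cols) matrix(stats::rnorm(n * cols), n, cols)
  # fields drawn in fixed order for reproducibility
  alpha_l <- noise(tt)
  beta_l <- noise(length(t_ext))
  g1_l <- noise(tt)
  g2_l <- noise(tt)
  g3_l <- noise(tt)
  alpha_s <- matrix(sqrt(2) * sin(w * t_obs), n, tt, byrow = TRUE)
  beta_s_ext <- matrix(sqrt(2) * cos(w * t_ext - phi * pi), n, length(t_ext),
                       byrow = TRUE)
  alpha <- a_s * alpha_s + a_l * alpha_l
  beta_ext <- a_s * beta_s_ext + a_l * beta_l
  beta <- beta_ext[, t_ext >= 0, drop = FALSE]
  beta_lagged <- beta_ext[, seq_len(tt), drop = FALSE]   # beta(n, t - 5)
  gamma1 <- a_s * (-alpha) + a_l * g1_l
  gamma2 <- a_s * (-beta_lagged) + a_l * g2_l
  gamma3 <- a_s * (-(alpha + beta_lagged) / f) + a_l * g3_l
  years <- seq_len(tt)
  ids <- paste0("loc", seq_len(n))
  structure(
    list(
      alpha = st_panel(alpha, ids, years),
      beta = st_panel(beta, ids, years),
      beta_lagged = st_panel(beta_lagged, ids, years),
      gamma1 = st_panel(gamma1, ids, years),
      gamma2 = st_panel(gamma2, ids, years),
      gamma3 = st_panel(gamma3, ids, years),
      phi = phi, f = f, w = w, period = 20, lag = lag, seed = seed
    ),
    class = "two_driver_scenario"
  )
}

#' @export
print.two_driver_scenario <- function(x, ...) {
  cat(sprintf(
    "<two_driver_scenario> phi = %.2f (f = %.4f), %d locations x %d years, seed %d\n",
    x$phi, x$f, nrow(x$alpha$values), ncol(x$alpha$values), x$seed
  ))
  invisible(x)
}

#' AR(1) population driven by correlated environmental fields
#'
#' Generates a population index following
#' `gamma(n, t) = a * gamma(n, t-1) + eps(n, t)` with driving noise
#' `eps = weight_alpha * alpha + weight_beta * beta`. Each driver is a
#' Gaussian field equicorrelated across locations (`rho_alpha`,
#' `rho_beta`), built as a shared common component plus independent local
#' components; `rho_between` correlates the two drivers' common
#' components. By the classical Moran argument, the cross-location
#' correlation of the stationary population equals the cross-location
#' correlation of `eps`.
#'
#' @param n_locations,n_years Panel dimensions of the returned series.
#' @param a AR(1) coefficient, `|a| < 1`.
#' @param weight_alpha,weight_beta Driver weights in `eps`.
#' @param rho_alpha,rho_beta Cross-location correlations of each driver.
#' @param rho_between Correlation between the drivers' common components.
#' @param seed Integer seed.
#' @param burn_in Initial steps discarded (default 100).
#' @return Object of class `"ar1_scenario"` with [st_panel()] elements
#'   `gamma`, `alpha`, `beta` and the parameters.
#' @export
generate_ar1_moran <- function(n_locations, n_years, a, weight_alpha = 1,
                               weight_beta = 0, rho_alpha = 0, rho_beta = 0,
                               rho_between = 0, seed = 1, burn_in = 100) {
  if (abs(a) >= 1) stop("AR(1) coefficient must satisfy |a| < 1")
  for (r in c(rho_alpha, rho_beta, rho_between)) {
    if (r < 0 || r > 1) stop("correlations must lie in [0, 1]")
  }
  n <- n_locations
  tt <- n_years + burn_in
  set.seed(seed)
  common <- matrix(stats::rnorm(2 * tt), 2)      # rows: alpha, beta commons
  common[2, ] <- rho_between * common[1, ] +
    sqrt(1 - rho_between^2) * common[2, ]
  field <- function(rho, common_row) {
    sqrt(rho) * matrix(common_row, n, tt, byrow = TRUE) +
      sqrt(1 - rho) * matrix(stats::rnorm(n * tt), n, tt)
  }
  alpha <- field(rho_alpha, common[1, ])
  beta <- field(rho_beta, common[2, ])
  eps <- weight_alpha * alpha + weight_beta * beta
  gamma <- matrix(0, n, tt)
  gamma[, 1] <- eps[, 1] / sqrt(1 - a^2)
  for (t in 2:tt) gamma[, t] <- a * gamma[, t - 1] + eps[, t]
  keep <- (burn_in + 1):tt
  years <- seq_len(n_years)
  ids <- paste0("loc", seq_len(n))
  structure(
    list(
      gamma = st_panel(gamma[, keep, drop = FALSE], ids, years),
      alpha = st_panel(alpha[, keep, drop = FALSE], ids, years),
      beta = st_panel(beta[, keep, drop = FALSE], ids, years),
      a = a, weight_alpha = weight_alpha, weight_beta = weight_beta,
      rho_alpha = rho_alpha, rho_beta = rho_beta, rho_between = rho_between,
      seed = seed
    ),
    class = "ar1_scenario"
  )
}

#' Generic synchronous-sinusoid-plus-noise panel
#'
#' Each location's series is
#' `sqrt(sync_fraction) * sqrt(2) * sin(2*pi*(t - lag)/period + phase) +
#' sqrt(1 - sync_fraction) * noise` with independent standard-normal
#' noise, generalizing the two-driver construction for property tests:
#' `sync_fraction` is the fraction of variance carried by the shared
#' sinusoid.
#'
#' @param n_locations,n_years Panel dimensions.
#' @param period Sinusoid period in years, in `[4, T/2]`.
#' @param sync_fraction Fraction of variance in the shared component,
#'   in `[0, 1]`.
#' @param lag,phase Time shift (years) and phase offset (radians) of the
#'   sinusoid.
#' @param seed Integer seed.
#' @return An [st_panel()].
#' @export
generate_sync_panel <- function(n_locations, n_years, period, sync_fraction,
                                lag = 0, phase = 0, seed = 1) {
  if (sync_fraction < 0 || sync_fraction > 1) {
    stop("`sync_fraction` must lie in [0, 1]")
  }
  if (period < 4 || period > n_years / 2) {
    stop("`period` must lie in [4, T/2]")
  }
  t_obs <- 0:(n_years - 1)
  set.seed(seed)
  shared <- sqrt(sync_fraction) * sqrt(2) *
    sin(2 * pi * (t_obs - lag) / period + phase)
  x <- matrix(shared, n_locations, n_years, byrow = TRUE) +
    sqrt(1 - sync_fraction) *
      matrix(stats::rnorm(n_locations * n_years), n_locations, n_years)
  st_panel(x, paste0("loc", seq_len(n_locations)), seq_len(n_years))
}
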