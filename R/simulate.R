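#' Specification of a synthetic daily fire-count series
#'
#' Defines the generating model for synthetic data: on the log scale the
#' series is a linear trend plus a sum of sinusoids (annual, 6-month,
#' 4-month, 3-month, 7-day and 3.5-day cycles by default), optional additive
#' weekday offsets, and a zero-mean stationary Gaussian AR noise process,
#' \deqn{Y_t = a_0 + a_1 t + \sum_i [c_i \cos(\omega_i t) +
#'   d_i \sin(\omega_i t)] + s_{w(t)} + X_t,}
#' where \eqn{w(t)} is the ISO weekday of day \eqn{t} and
#' \eqn{X_t = \sum_k \phi_k X_{t-k} + Z_t} with white noise
#' \eqn{Z_t \sim N(0, \sigma_Z^2)}.
#'
#' The default coefficient values are a preset calibrated to the global
#' daily vegetation-fire count series (a ten-year record of roughly 11,000
#' fires per day): intercept about 9.34 on the log scale, a negligible
#' trend, a dominant annual cycle with three sub-annual harmonics, and weak
#' weekly and half-weekly harmonics. The default AR(7) coefficients and
#' innovation standard deviation are plausible placeholders chosen so the
#' realised noise has a standard deviation of roughly 0.15 log units (the
#' published analyses of this series do not report the fitted noise
#' parameters); see the package vignette.
#'
#' @param n_days number of days to simulate (default 3675 = 525 weeks).
#' @param start_date first calendar day; the default, 2002-07-08, is a
#'   Monday, so day 1 is a Monday.
#' @param a0 intercept on the log-count scale.
#' @param a1 linear trend per day on the log scale.
#' @param harmonics data frame (or list coercible to one) with columns
#'   `omega` (angular frequency, rad/day, in (0, pi)), `cos` and `sin`
#'   (coefficients \eqn{c_i}, \eqn{d_i}).
#' @param weekday_offsets numeric vector of 7 additive log-scale offsets,
#'   index 1 = Monday ... 7 = Sunday.
#' @param ar_coefficients numeric vector of up to 7 AR coefficients
#'   \eqn{\phi_k}; must define a stationary process.
#' @param innovation_sd positive innovation standard deviation
#'   \eqn{\sigma_Z}.
#' @param count_mode how log-scale values become counts:
#'   `"round-lognormal"` rounds \eqn{\exp(Y_t)}; `"poisson"` draws
#'   Poisson(\eqn{\exp(Y_t)}).
#' @param seed integer seed used by the simulators.
#' @return A validated object of class `simulation_spec`.
#' @examples
#' spec <- simulation_spec(n_days = 28, seed = 42)
#' sim <- simulate_log_series(spec)
#' @export
simulation_spec <- function(n_days = 3675L,
                            start_date = as.Date("2002-07-08"),
                            a0 = 9.3405,
                            a1 = -2.3729e-05,
                            harmonics = default_harmonics(),
                            weekday_offsets = rep(0, 7),
                            ar_coefficients = c(0.35, 0.10, 0.05, 0.03,
                                                0.02, 0.01, 0.10),
                            innovation_sd = 0.12,
                            count_mode = c("round-lognormal", "poisson"),
                            seed = 1L) {
  count_mode <- match.arg(count_mode)
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop("'n_days' must be >= 1")
  start_date <- as.Date(start_date)
  harmonics <- as.data.frame(harmonics)
  if (nrow(harmonics) > 0) {
    if (!all(c("omega", "cos", "sin") %in% names(harmonics)))
      stop("'harmonics' needs columns omega, cos, sin")
    if (any(harmonics$omega <= 0 | harmonics$omega >= pi))
      stop("all angular frequencies must lie in (0, pi)")
  }
  if (length(weekday_offsets) != 7L)
    stop("'weekday_offsets' must have length 7 (Monday..Sunday)")
  if (!is.null(ar_coefficients) && length(ar_coefficients) > 0) {
    if (length(ar_coefficients) > 7L)
      stop("at most 7 AR coefficients are supported")
    if (!ar_is_stationary(ar_coefficients))
      stop("AR coefficients define a non-stationary process: ",
           "the polynomial 1 - sum(phi_i z^i) has a root inside or on ",
           "the unit circle")
  } else {
    ar_coefficients <- numeric(0)
  }
  if (!is.finite(innovation_sd) || innovation_sd <= 0)
    stop("'innovation_sd' must be > 0")
  structure(list(n_days = n_days, start_date = start_date,
                 a0 = a0, a1 = a1, harmonics = harmonics,
                 weekday_offsets = as.numeric(weekday_offsets),
                 ar_coefficients = as.numeric(ar_coefficients),
                 innovation_sd = innovation_sd,
                 count_mode = count_mode, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Default harmonic terms of the synthetic preset
#'
#' Six sinusoids: the annual cycle and its first three harmonics (6-, 4-
#' and 3-month periods) plus the weekly and half-weekly cycles, with
#' coefficients matching the fitted global fire-count model.
#'
#' @return Data frame with columns `omega`, `cos`, `sin`.
#' @export
default_harmonics <- function() {
  data.frame(
    omega = c(2 * pi / 365, 4 * pi / 365, 6 * pi / 365, 8 * pi / 365,
              2 * pi / 7, 4 * pi / 7),
    cos = c(0.18654, 0.17998, -0.047871, -0.0067088, -0.042395, -0.033660),
    sin = c(0.26376, 0.11867, 0.13137, -0.086432, 0.010734, -0.010493)
  )
}

# stationarity: all roots of 1 - sum(phi_i z^i) outside the unit circle
ar_is_stationary <- function(phi, tol = 1e-8) {
  phi <- as.numeric(phi)
  if (length(phi) == 0 || all(phi == 0)) return(TRUE)
  roots <- polyroot(c(1, -phi))
  all(Mod(roots) > 1 + tol)
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(paste0("<simulation_spec> %d days from %s; a0=%.4f a1=%.3g; ",
                     "%d harmonics; AR(%d) sd=%.3g; mode=%s; seed=%d\n"),
              x$n_days, format(x$start_date), x$a0, x$a1,
              nrow(x$harmonics), length(x$ar_coefficients),
              x$innovation_sd, x$count_mode, x$seed))
  invisible(x)
}

# noiseless mean on the log scale, including weekday offsets
spec_mean_function <- function(spec, t = seq_len(spec$n_days)) {
  m <- spec$a0 + spec$a1 * t
  h <- spec$harmonics
  if (nrow(h) > 0) {
    for (i in seq_len(nrow(h))) {
      m <- m + h$cos[i] * cos(h$omega[i] * t) +
        h$sin[i] * sin(h$omega[i] * t)
    }
  }
  wd <- iso_weekday(spec$start_date + (t - 1))
  m + spec$weekday_offsets[wd]
}

# stationary AR draw with burn-in discarded
simulate_ar_noise <- function(n, phi, sd, burn = 500L) {
  p <- length(phi)
  if (p == 0) return(stats::rnorm(n, sd = sd))
  total <- n + burn
  z <- stats::rnorm(total, sd = sd)
  x <- numeric(total)
  for (t in seq_len(total)) {
    acc <- z[t]
    for (k in seq_len(min(p, t - 1))) acc <- acc + phi[k] * x[t - k]
    x[t] <- acc
  }
  x[(burn + 1):total]
}

#' Simulate a log-scale daily series
#'
#' Draws one realisation of the generating model in [simulation_spec()]:
#' deterministic mean function plus weekday offsets plus a stationary AR
#' noise draw (a burn-in of 500 steps is discarded). Reproducible given
#' the spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return A list with `series` (a [log_counts()] object) and `true_mean`
#'   (the noiseless mean vector, weekday offsets included).
#' @export
simulate_log_series <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  m <- spec_mean_function(spec)
  x <- simulate_ar_noise(spec$n_days, spec$ar_coefficients,
                         spec$innovation_sd)
  list(series = log_counts(m + x, spec$start_date, "synthetic"),
       true_mean = m)
}

#' Simulate a daily count series
#'
#' Realises [simulate_log_series()] on the count scale: counts are
#' `round(exp(y))` in `"round-lognormal"` mode or Poisson draws with mean
#' `exp(y)` in `"poisson"` mode.
#'
#' @param spec a [simulation_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return A [daily_counts()] object of length `spec$n_days`.
#' @export
simulate_count_series <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  sim <- simulate_log_series(spec, seed = seed)
  lambda <- exp(sim$series$values)
  bad <- which(!is.finite(lambda) | lambda > 2^53)
  if (length(bad) > 0)
    stop("exp(y_t) overflows at t = ", bad[1],
         " (log value ", signif(sim$series$values[bad[1]], 4), ")")
  counts <- switch(spec$count_mode,
    "round-lognormal" = round(lambda),
    "poisson" = stats::rpois(length(lambda), lambda))
  daily_counts(counts, spec$start_date, "synthetic")
}
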