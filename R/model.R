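#' Harmonic regression design matrix
#'
#' Columns: intercept, linear trend `t`, then `cos(omega_i t)`,
#' `sin(omega_i t)` per frequency, for `t = 1..n` (or an explicit vector
#' of time indices).
#'
#' @param n number of days (ignored when `t` is given).
#' @param freqs a [frequency_set()] or numeric vector of angular
#'   frequencies.
#' @param t optional integer vector of time indices.
#' @return Numeric matrix with `2 + 2k` named columns.
#' @export
build_design <- function(n, freqs, t = seq_len(n)) {
  omega <- if (inherits(freqs, "frequency_set")) freqs$omega else
    as.numeric(freqs)
  k <- length(omega)
  X <- matrix(0, length(t), 2 + 2 * k)
  X[, 1] <- 1
  X[, 2] <- t
  nm <- c("a0", "a1")
  for (i in seq_len(k)) {
    X[, 2 * i + 1] <- cos(omega[i] * t)
    X[, 2 * i + 2] <- sin(omega[i] * t)
    nm <- c(nm, paste0("c", i), paste0("d", i))
  }
  colnames(X) <- nm
  X
}

#' Autoregressive noise parameters
#'
#' @param phi numeric vector of AR coefficients (order = length), must be
#'   stationary.
#' @param sigma positive innovation standard deviation.
#' @return An object of class `ar_params`.
#' @export
ar_params <- function(phi, sigma) {
  phi <- as.numeric(phi)
  if (length(phi) > 0 && !ar_is_stationary(phi))
    stop("AR coefficients are non-stationary")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  structure(list(order = length(phi), phi = phi, sigma = sigma),
            class = "ar_params")
}

#' @export
print.ar_params <- function(x, ...) {
  cat(sprintf("<ar_params> AR(%d), sigma_Z = %.4g\n", x$order, x$sigma))
  if (x$order > 0)
    cat("  phi:", paste(sprintf("%.4f", x$phi), collapse = " "), "\n")
  invisible(x)
}

#' Fit an AR model by the Burg method
#'
#' Burg estimates are stationary by construction; the innovation variance
#' is the final prediction-error variance. Order 0 returns an empty
#' coefficient vector with sigma equal to the residual standard
#' deviation.
#'
#' @param x numeric vector (or [log_counts()]) of residuals.
#' @param order AR order (0..7 in the intended use).
#' @return An [ar_params()].
#' @export
fit_ar <- function(x, order) {
  y <- if (inherits(x, "log_counts")) x$values else as.numeric(x)
  if (length(y) <= 10 * max(order, 1))
    stop("series too short for AR order ", order)
  if (stats::sd(y) == 0) stop("degenerate (zero-variance) residuals")
  if (order == 0)
    return(ar_params(numeric(0), sqrt(mean((y - mean(y))^2))))
  fit <- stats::ar.burg(y, aic = FALSE, order.max = order,
                        demean = TRUE)
  ar_params(as.numeric(fit$ar), sqrt(fit$var.pred))
}

#' Select an AR order by AIC over Burg fits
#'
#' @param x numeric vector (or [log_counts()]) of residuals.
#' @param max_order largest order considered.
#' @return The selected order (integer, possibly 0).
#' @export
select_ar_order <- function(x, max_order = 14L) {
  y <- if (inherits(x, "log_counts")) x$values else as.numeric(x)
  if (max_order == 0) return(0L)
  fit <- stats::ar.burg(y, aic = TRUE, order.max = max_order,
                        demean = TRUE)
  as.integer(fit$order)
}

#' Prior specification for the fixed effects
#'
#' Independent zero-mean normal priors with a common precision on the
#' trend and harmonic coefficients, and (by default) a flat prior on the
#' intercept. Individual precisions can be overridden per coefficient,
#' e.g. to pin a coefficient at zero with an effectively infinite
#' precision.
#'
#' @param fixed_precision common prior precision (default 0.001, i.e. a
#'   vague prior).
#' @param intercept_flat flat (zero-precision) prior for `a0`?
#' @param precisions optional named numeric vector overriding the
#'   precision of individual coefficients (names as in the design:
#'   `a0`, `a1`, `c1`, `d1`, ...).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(fixed_precision = 0.001, intercept_flat = TRUE,
                       precisions = NULL) {
  if (fixed_precision < 0) stop("'fixed_precision' must be >= 0")
  structure(list(fixed_precision = fixed_precision,
                 intercept_flat = intercept_flat,
                 precisions = precisions),
            class = "prior_spec")
}

prior_precision_vector <- function(priors, coef_names) {
  p <- rep(priors$fixed_precision, length(coef_names))
  names(p) <- coef_names
  if (priors$intercept_flat) p["a0"] <- 0
  if (!is.null(priors$precisions)) {
    known <- intersect(names(priors$precisions), coef_names)
    p[known] <- priors$precisions[known]
  }
  p
}

# Durbin-Levinson step-up: partial autocorrelations -> AR coefficients
pacf_to_ar <- function(r) {
  phi <- numeric(0)
  for (k in seq_along(r)) {
    phi <- if (k == 1) r[1] else c(phi - r[k] * rev(phi), r[k])
  }
  phi
}

# step-down inverse: AR coefficients -> partial autocorrelations
ar_to_pacf <- function(phi) {
  p <- length(phi)
  r <- numeric(p)
  a <- phi
  for (k in rev(seq_len(p))) {
    r[k] <- a[k]
    if (k > 1) a <- (a[-k] + r[k] * rev(a[-k])) / (1 - r[k]^2)
  }
  r
}

# conditional REML estimation of (phi, sigma) for the regression with AR
# errors: minimise (m - q) log RSS(phi) + log det(Xt' Xt) over the
# atanh-transformed partial autocorrelations (stationary by construction),
# with sigma^2 profiled out as RSS / (m - q). Returns NULL if the
# optimiser fails, in which case the caller keeps the Burg estimates.
reml_polish <- function(y, X, phi0) {
  n <- length(y)
  p <- length(phi0)
  q <- ncol(X)
  obj <- function(theta) {
    phi <- pacf_to_ar(tanh(theta))
    Xt <- ar_whiten(X, phi)
    yt <- ar_whiten(matrix(y, ncol = 1), phi)
    qrX <- qr(Xt)
    rss <- sum(qr.resid(qrX, yt)^2)
    (n - p - q) * log(rss) + 2 * sum(log(abs(diag(qr.R(qrX)))))
  }
  theta0 <- atanh(pmin(pmax(ar_to_pacf(phi0), -0.99), 0.99))
  o <- tryCatch(
    stats::optim(theta0, obj, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(o) || o$convergence != 0) return(NULL)
  phi <- pacf_to_ar(tanh(o$par))
  Xt <- ar_whiten(X, phi)
  yt <- ar_whiten(matrix(y, ncol = 1), phi)
  rss <- sum(qr.resid(qr(Xt), yt)^2)
  list(phi = phi, sigma = sqrt(rss / (n - p - q)))
}

# apply the AR whitening filter: row t -> row t - sum(phi_k * row (t-k)),
# dropping the first p rows (conditional likelihood)
ar_whiten <- function(mat, phi) {
  p <- length(phi)
  if (p == 0) return(mat)
  mat <- as.matrix(mat)
  n <- nrow(mat)
  out <- mat[(p + 1):n, , drop = FALSE]
  for (k in seq_len(p))
    out <- out - phi[k] * mat[(p + 1 - k):(n - k), , drop = FALSE]
  out
}

#' Fit the harmonic regression with AR errors
#'
#' Empirical-Bayes fit of the model \eqn{Y_t = M_t + X_t} with mean
#' function \eqn{M_t = a_0 + a_1 t + \sum_i [c_i \cos \omega_i t + d_i
#' \sin \omega_i t]} and stationary Gaussian AR(p) errors. The algorithm
#' alternates (1) the exact conjugate Gaussian posterior of the fixed
#' effects conditional on the current AR parameters, obtained by AR-
#' whitening the response and design (dropping the first p rows), and (2)
#' a Burg refit of the AR parameters on the posterior-mean residuals,
#' until the AR coefficients change by less than `tol`. The AR parameters
#' are then polished by restricted maximum likelihood (conditional REML,
#' optimised over partial autocorrelations so stationarity holds by
#' construction): naive refits on regression residuals underestimate the
#' noise spectrum near the design frequencies, because the fitted mean
#' absorbs part of the low-frequency noise, and the REML determinant term
#' restores exactly the degrees of freedom the regression consumes. The
#' final coefficient posterior is exactly Gaussian conditional on the
#' REML noise parameters.
#'
#' @param series a [log_counts()].
#' @param freqs a [frequency_set()] (defaults to the six nominal cycle
#'   frequencies).
#' @param ar_order AR order for the noise (default 7).
#' @param priors a [prior_spec()].
#' @param max_iter maximum alternation steps.
#' @param tol convergence tolerance on `max |delta phi|`.
#' @param ar_uncertainty `"delta"` (default) adds a first-order
#'   Kass-Steffey-type correction for the uncertainty of the plugged-in
#'   AR coefficients to the coefficient posterior covariance (the
#'   delta-method term `J V_phi J'`, with `J` the sensitivity of the
#'   posterior mean to the AR coefficients and `V_phi` their asymptotic
#'   sampling covariance); `"none"` reports the purely conditional
#'   covariance.
#' @param noise_estimator `"reml"` (default) polishes the AR coefficients
#'   and innovation sd by conditional REML after the Burg alternation
#'   converges; `"burg"` keeps the plain plug-in Burg estimates.
#' @return An object of class `harmonic_ar_fit` with elements
#'   `coef_mean`, `coef_cov`, `ar` (an [ar_params()]), `residuals`
#'   (posterior-mean residuals, a [log_counts()]), `freqs`, `converged`,
#'   `iterations`, `gram_condition` and the input metadata.
#' @export
fit_bayes_harmonic_ar <- function(series, freqs = nominal_frequencies(),
                                  ar_order = 7L, priors = prior_spec(),
                                  max_iter = 20L, tol = 1e-4,
                                  ar_uncertainty = c("delta", "none"),
                                  noise_estimator = c("reml", "burg")) {
  ar_uncertainty <- match.arg(ar_uncertainty)
  noise_estimator <- match.arg(noise_estimator)
  stopifnot(inherits(series, "log_counts"))
  y <- series$values
  n <- length(y)
  X <- build_design(n, freqs)
  q <- ncol(X)
  if (n <= q + ar_order + 10)
    stop("series too short: n = ", n, " for ", q,
         " coefficients and AR order ", ar_order)
  # column scaling for numerical stability (t runs to n)
  scales <- sqrt(colMeans(X^2))
  Xs <- sweep(X, 2, scales, "/")
  prec <- prior_precision_vector(priors, colnames(X))
  # scaled coefficient is scales[j] * beta_j, so its prior precision is
  # the original precision divided by scales[j]^2
  prec_s <- prec / scales^2

  posterior <- function(phi, sigma) {
    yt <- ar_whiten(matrix(y, ncol = 1), phi)
    Xt <- ar_whiten(Xs, phi)
    G <- crossprod(Xt)
    A <- G / sigma^2 + diag(prec_s, q)
    R <- chol(A)
    cov_s <- chol2inv(R)
    mean_s <- drop(cov_s %*% (crossprod(Xt, yt) / sigma^2))
    list(mean_s = mean_s, cov_s = cov_s,
         cond = kappa(G, exact = FALSE))
  }

  phi <- numeric(0)
  sigma <- stats::sd(y)
  converged <- FALSE
  iterations <- 0L
  post <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    post <- posterior(phi, sigma)
    resid <- y - drop(Xs %*% post$mean_s)
    if (ar_order == 0) {
      arfit <- fit_ar(resid, 0L)
      phi_new <- numeric(0)
    } else {
      arfit <- fit_ar(resid, ar_order)
      phi_new <- arfit$phi
    }
    sigma <- arfit$sigma
    delta <- if (length(phi) == length(phi_new))
      max(abs(phi_new - phi), 0) else Inf
    phi <- phi_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("AR coefficients did not converge in ", max_iter,
            " iterations")
  if (noise_estimator == "reml" && length(phi) > 0) {
    polished <- reml_polish(y, Xs, phi)
    if (!is.null(polished)) {
      phi <- polished$phi
      sigma <- polished$sigma
    }
  }
  post <- posterior(phi, sigma)
  resid <- y - drop(Xs %*% post$mean_s)
  cov_s <- post$cov_s
  if (ar_uncertainty == "delta" && length(phi) > 0) {
    # Kass-Steffey first-order correction: the conditional posterior
    # ignores that phi is estimated; add Var_phi(E[beta | phi]) by the
    # delta method with the asymptotic Burg covariance
    # V_phi = sigma^2 Gamma_p^{-1} / n_eff
    p <- length(phi)
    rho <- stats::ARMAacf(ar = phi, lag.max = p)
    gamma0 <- sigma^2 / (1 - sum(phi * rho[-1]))
    Gam <- gamma0 * stats::toeplitz(rho[seq_len(p)])
    Vphi <- sigma^2 * solve(Gam) / (n - p)
    h <- 1e-5
    J <- matrix(0, q, p)
    for (k in seq_len(p)) {
      phi_h <- phi
      phi_h[k] <- phi_h[k] + h
      J[, k] <- (posterior(phi_h, sigma)$mean_s - post$mean_s) / h
    }
    cov_s <- cov_s + J %*% Vphi %*% t(J)
  }
  coef_mean <- post$mean_s / scales
  coef_cov <- sweep(sweep(cov_s, 1, scales, "/"), 2, scales, "/")
  dimnames(coef_cov) <- list(colnames(X), colnames(X))
  names(coef_mean) <- colnames(X)
  structure(list(coef_mean = coef_mean, coef_cov = coef_cov,
                 ar = ar_params(phi, sigma),
                 residuals = log_counts(resid, series$start_date,
                                        paste0(series$label,
                                               " (residuals)")),
                 freqs = if (inherits(freqs, "frequency_set")) freqs else
                   frequency_set(freqs),
                 n = n, start_date = series$start_date,
                 label = series$label, priors = priors,
                 converged = converged, iterations = iterations,
                 gram_condition = post$cond),
            class = "harmonic_ar_fit")
}

#' @export
print.harmonic_ar_fit <- function(x, ...) {
  cat(sprintf(paste0("<harmonic_ar_fit> '%s': n=%d, %d fixed effects, ",
                     "AR(%d) sigma_Z=%.4g, %sconverged in %d iteration(s)\n"),
              x$label, x$n, length(x$coef_mean), x$ar$order, x$ar$sigma,
              if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Posterior summary table for the fixed effects
#'
#' Gaussian marginal summaries (mean, sd, 2.5/50/97.5 percent quantiles
#' and mode, which equals the mean for a Gaussian). A coefficient is
#' flagged not significant when 0 lies inside its central 95 percent
#' interval.
#'
#' @param fit a [fit_bayes_harmonic_ar()] result.
#' @return Data frame with one row per coefficient.
#' @export
summarize_fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "harmonic_ar_fit"))
  mu <- fit$coef_mean
  sd <- sqrt(pmax(diag(fit$coef_cov), 0))
  lo <- mu + stats::qnorm(0.025) * sd
  hi <- mu + stats::qnorm(0.975) * sd
  data.frame(name = names(mu), mean = unname(mu), sd = unname(sd),
             q0.025 = unname(lo), q0.5 = unname(mu), q0.975 = unname(hi),
             mode = unname(mu),
             significant = unname(!(lo <= 0 & 0 <= hi)))
}

#' Write the fixed-effects summary to CSV
#'
#' Uses the conventional column set `mean, sd, 0.025quant, 0.5quant,
#' 0.975quant, mode`.
#'
#' @param fit a [fit_bayes_harmonic_ar()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixed_effects_csv <- function(fit, path) {
  s <- summarize_fixed_effects(fit)
  out <- data.frame(name = s$name, mean = s$mean, sd = s$sd,
                    check.names = FALSE)
  out[["0.025quant"]] <- s$q0.025
  out[["0.5quant"]] <- s$q0.5
  out[["0.975quant"]] <- s$q0.975
  out[["mode"]] <- s$mode
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Multivariate-normal posterior of the mean function
#'
#' Evaluates the posterior of \eqn{M_t} over a time window:
#' mean `D mu` and covariance `D Sigma D'` for the design rows `D` of the
#' window. The covariance is symmetrized and has rank at most the number
#' of fixed effects.
#'
#' @param fit a [fit_bayes_harmonic_ar()] result.
#' @param window integer vector of time indices (default `1:364`, the
#'   first 52 weeks). Indices beyond the fitted range are allowed but
#'   flagged with a warning (extrapolation).
#' @return An object of class `mean_fn_posterior` with fields `t`,
#'   `mean`, `cov`, `start_date` (calendar date of t = 1) and `label`.
#' @export
mean_function_posterior <- function(fit, window = 1:364) {
  stopifnot(inherits(fit, "harmonic_ar_fit"))
  if (any(window < 1))
    stop("'window' indices must be >= 1")
  if (any(window > fit$n))
    warning("window extends beyond the fitted series (extrapolation)")
  D <- build_design(fit$n, fit$freqs, t = window)
  m <- drop(D %*% fit$coef_mean)
  S <- D %*% fit$coef_cov %*% t(D)
  S <- (S + t(S)) / 2
  structure(list(t = as.integer(window), mean = m, cov = S,
                 start_date = fit$start_date, label = fit$label),
            class = "mean_fn_posterior")
}

#' @export
print.mean_fn_posterior <- function(x, ...) {
  cat(sprintf(paste0("<mean_fn_posterior> '%s': %d time points ",
                     "(t = %d..%d), mean in [%.4f, %.4f]\n"),
              x$label, length(x$t), min(x$t), max(x$t),
              min(x$mean), max(x$mean)))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Flat-text snapshot of the fit (coefficients, covariance, AR
#' parameters, frequencies) that can be stored alongside pipeline
#' outputs.
#'
#' @param fit a [fit_bayes_harmonic_ar()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  obj <- list(label = fit$label, n = fit$n,
              start_date = format(fit$start_date),
              coef_mean = as.list(fit$coef_mean),
              coef_cov = unname(as.matrix(fit$coef_cov)),
              ar_phi = fit$ar$phi, ar_sigma = fit$ar$sigma,
              omega = fit$freqs$omega, converged = fit$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
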