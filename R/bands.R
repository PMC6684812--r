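# Cholesky factor with a deterministic PSD jitter fallback
chol_with_jitter <- function(S, jitter = 1e-10) {
  S <- as.matrix(S)
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) {
    scale <- max(diag(S), 1)
    out <- tryCatch(chol(S + diag(jitter * scale, nrow(S))),
                    error = function(e) NULL)
  }
  if (is.null(out))
    stop("covariance matrix is not positive semi-definite ",
         "(Cholesky failed even after jitter ", jitter, ")")
  out
}

# draw n_mc samples of max_t |Z_t| / sd_t for Z ~ MVN(0, S), chunked to
# bound memory; components with zero variance never constrain the max
mvn_max_abs_standardized <- function(S, n_mc, seed, chunk = 20000L) {
  d <- nrow(S)
  sds <- sqrt(pmax(diag(S), 0))
  pos <- sds > 0
  L <- chol_with_jitter(S)
  set.seed(seed)
  out <- numeric(n_mc)
  done <- 0L
  while (done < n_mc) {
    k <- min(chunk, n_mc - done)
    Z <- matrix(stats::rnorm(k * d), k, d) %*% L
    if (any(pos)) {
      Zs <- abs(Z[, pos, drop = FALSE]) /
        rep(sds[pos], each = k)
      jmax <- max.col(Zs, ties.method = "first")
      out[(done + 1):(done + k)] <- Zs[cbind(seq_len(k), jmax)]
    }
    done <- done + k
  }
  out
}

#' Simultaneous HPD credible band for a Gaussian mean-function posterior
#'
#' Builds the hyper-rectangular band \eqn{\hat M_t \pm z \sqrt{S_{tt}}}
#' whose joint coverage under the multivariate-normal posterior is
#' \eqn{1 - \alpha}: the pointwise level \eqn{1 - \gamma} (with
#' \eqn{\gamma = 2(1 - \Phi(z))}) is tuned until the Monte-Carlo estimate
#' of \eqn{P(|M_t - \hat M_t| \le z \sqrt{S_{tt}}\ \forall t)} reaches
#' \eqn{1-\alpha}. The same MC draws are reused across the bisection
#' (common random numbers), which makes the estimated coverage monotone
#' in `z`; the bisection bracket `[qnorm(1-alpha/2), qnorm(1-alpha/(2n))]`
#' (pointwise and Bonferroni limits) provably contains the solution.
#'
#' @param mfp a [mean_function_posterior()] (or any list with fields
#'   `mean` and `cov`).
#' @param alpha joint miscoverage (default 0.05).
#' @param n_mc Monte-Carlo sample size.
#' @param seed integer seed.
#' @param tol acceptable deviation of the achieved MC coverage from
#'   `1 - alpha`.
#' @return An object of class `credible_band` with fields `z`, `gamma`,
#'   `alpha`, `lower`, `upper`, `mean`, `sds`, `coverage_estimate`,
#'   `n_mc`, `seed`, `t`.
#' @export
simultaneous_band <- function(mfp, alpha = 0.05, n_mc = 100000L,
                              seed = 1L, tol = 0.002) {
  m <- mfp$mean
  S <- as.matrix(mfp$cov)
  d <- length(m)
  stopifnot(nrow(S) == d, ncol(S) == d)
  sds <- sqrt(pmax(diag(S), 0))
  target <- 1 - alpha
  lo <- stats::qnorm(1 - alpha / 2)
  hi <- stats::qnorm(1 - alpha / (2 * d))
  if (d == 1 || all(sds == 0)) {
    # a single (or fully degenerate) component: the pointwise interval is
    # exact, no Monte-Carlo tuning needed
    z <- lo
    return(structure(list(alpha = alpha,
                          gamma = 2 * (1 - stats::pnorm(z)), z = z,
                          lower = m - z * sds, upper = m + z * sds,
                          mean = m, sds = sds,
                          coverage_estimate = 1 - alpha,
                          n_mc = 0L, seed = seed,
                          t = if (!is.null(mfp$t)) mfp$t else
                            seq_along(m),
                          start_date = mfp$start_date),
                     class = "credible_band"))
  }
  maxabs <- mvn_max_abs_standardized(S, n_mc, seed)
  coverage <- function(z) mean(maxabs <= z)
  if (coverage(lo) >= target - tol) {
    z <- lo
  } else {
    if (coverage(hi) < target - tol)
      stop("bisection bracket does not contain the target coverage")
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (coverage(mid) < target) lo <- mid else hi <- mid
      if (hi - lo < 1e-6) break
    }
    z <- hi
  }
  structure(list(alpha = alpha, gamma = 2 * (1 - stats::pnorm(z)),
                 z = z, lower = m - z * sds, upper = m + z * sds,
                 mean = m, sds = sds,
                 coverage_estimate = coverage(z),
                 n_mc = n_mc, seed = seed,
                 t = if (!is.null(mfp$t)) mfp$t else seq_along(m),
                 start_date = mfp$start_date),
            class = "credible_band")
}

#' @export
print.credible_band <- function(x, ...) {
  cat(sprintf(paste0("<credible_band> %d points, joint level %.3f ",
                     "(z = %.4f, pointwise gamma = %.5f, ",
                     "MC coverage %.4f from %d draws)\n"),
              length(x$mean), 1 - x$alpha, x$z, x$gamma,
              x$coverage_estimate, x$n_mc))
  invisible(x)
}

#' Monte-Carlo probability estimate
#'
#' @param estimate probability estimate in `[0, 1]`.
#' @param se binomial Monte-Carlo standard error.
#' @param n_mc,seed sampling metadata.
#' @return An object of class `prob_estimate`.
#' @export
prob_estimate <- function(estimate, se, n_mc, seed) {
  structure(list(estimate = estimate, se = se, n_mc = n_mc, seed = seed),
            class = "prob_estimate")
}

#' @export
print.prob_estimate <- function(x, ...) {
  cat(sprintf("<prob_estimate> %.4f (%.4f) from %d draws\n",
              x$estimate, x$se, x$n_mc))
  invisible(x)
}

mvn_event_probability <- function(mean, cov, event, n_mc, seed,
                                  chunk = 20000L) {
  d <- length(mean)
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  L <- chol_with_jitter(cov)
  # zero-variance components are deterministic at their mean; the jitter
  # used to factor a singular matrix must not perturb them
  L[, diag(cov) <= 0] <- 0
  set.seed(seed)
  hits <- 0
  done <- 0L
  while (done < n_mc) {
    k <- min(chunk, n_mc - done)
    X <- matrix(stats::rnorm(k * d), k, d) %*% L +
      rep(mean, each = k)
    hits <- hits + sum(event(X))
    done <- done + k
  }
  p <- hits / n_mc
  prob_estimate(p, sqrt(p * (1 - p) / n_mc), n_mc, seed)
}

#' Rectangle probability of a multivariate normal
#'
#' Monte-Carlo estimate of \eqn{P(LB \le X \le UB)} componentwise for
#' \eqn{X \sim MVN(mean, cov)}, with the binomial standard error
#' \eqn{\sqrt{\hat p (1 - \hat p)/n}}. This is the band-membership
#' probability when the bounds are a credible-band segment.
#'
#' @param mean mean vector.
#' @param cov covariance matrix (PSD; a deterministic jitter of 1e-10
#'   relative to the diagonal scale is applied if it is numerically
#'   singular).
#' @param lower,upper bound vectors (`lower <= upper` componentwise;
#'   equal bounds arise at zero-variance points and admit only exact
#'   ties).
#' @param n_mc Monte-Carlo sample size.
#' @param seed integer seed.
#' @return A [prob_estimate()].
#' @export
interval_probability <- function(mean, cov, lower, upper,
                                 n_mc = 100000L, seed = 1L) {
  d <- length(mean)
  if (length(lower) != d || length(upper) != d)
    stop("dimension mismatch between mean and bounds")
  if (any(lower > upper))
    stop("'lower' must be <= 'upper' componentwise")
  mvn_event_probability(mean, cov, function(X) {
    rowSums(X >= rep(lower, each = nrow(X)) &
              X <= rep(upper, each = nrow(X))) == d
  }, n_mc, seed)
}

#' Joint exceedance probability of a multivariate normal
#'
#' Monte-Carlo estimate of \eqn{P(X_t > threshold_t\ \forall t)} for
#' \eqn{X \sim MVN(mean, cov)}. The inequality is strict; exact ties
#' count as not above.
#'
#' @inheritParams interval_probability
#' @param threshold threshold vector.
#' @return A [prob_estimate()].
#' @export
exceedance_probability <- function(mean, cov, threshold,
                                   n_mc = 100000L, seed = 1L) {
  d <- length(mean)
  if (length(threshold) != d)
    stop("dimension mismatch between mean and threshold")
  mvn_event_probability(mean, cov, function(X) {
    rowSums(X > rep(threshold, each = nrow(X))) == d
  }, n_mc, seed)
}

#' Write a credible band to CSV
#'
#' Columns: `t`, `date` (when the band carries a start date), `mean`,
#' `lower`, `upper`.
#'
#' @param band a [simultaneous_band()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_band_csv <- function(band, path) {
  df <- data.frame(t = band$t)
  if (!is.null(band$start_date))
    df$date <- format(band$start_date + (band$t - 1))
  df$mean <- band$mean
  df$lower <- band$lower
  df$upper <- band$upper
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
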