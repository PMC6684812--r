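#' Log-transform a daily count series
#'
#' @param series a [daily_counts()].
#' @param offset 0 or 1; added to the counts before taking logs. Series
#'   containing zero counts must use `offset = 1`.
#' @return A [log_counts()] with `y_t = log(count_t + offset)`.
#' @export
log_transform <- function(series, offset = 0) {
  stopifnot(inherits(series, "daily_counts"))
  if (!offset %in% c(0, 1)) stop("'offset' must be 0 or 1")
  if (offset == 0 && any(series$counts == 0))
    stop("series contains zero counts; use offset = 1")
  log_counts(log(series$counts + offset), series$start_date, series$label)
}

#' Periodogram at Fourier frequencies
#'
#' Computes \eqn{I(\omega_j) = n^{-1} |\sum_t (y_t - \bar y)
#' e^{-i t \omega_j}|^2} at the Fourier frequencies
#' \eqn{\omega_j = 2\pi j / n}, \eqn{j = 1, \dots, \lfloor (n-1)/2
#' \rfloor}. The series is mean-centered internally. The ordinates satisfy
#' Parseval's identity: twice their sum (plus the Nyquist ordinate once,
#' for even n) equals the centered sum of squares.
#'
#' @param series a [log_counts()] or numeric vector, length >= 3.
#' @return An object of class `periodogram` with fields `n`, `index`,
#'   `omega`, `ordinate`.
#' @export
periodogram <- function(series) {
  y <- if (inherits(series, "log_counts")) series$values else
    as.numeric(series)
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  y <- y - mean(y)
  d <- stats::fft(y)
  m <- (n - 1) %/% 2
  j <- seq_len(m)
  structure(list(n = n, index = j, omega = 2 * pi * j / n,
                 ordinate = Mod(d[j + 1])^2 / n),
            class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  top <- order(x$ordinate, decreasing = TRUE)[1:min(3, length(x$ordinate))]
  cat(sprintf("<periodogram> n=%d, %d ordinates; top periods (days): %s\n",
              x$n, length(x$ordinate),
              paste(sprintf("%.2f", 2 * pi / x$omega[top]), collapse = ", ")))
  invisible(x)
}

#' Exact null p-value of Fisher's g statistic
#'
#' Evaluates \eqn{P(g_{max} > g) = \sum_{j=1}^{\lfloor 1/g \rfloor}
#' (-1)^{j-1} \binom{m}{j} (1 - jg)^{m-1}} for the maximum normalised
#' periodogram ordinate among `m` under the Gaussian white-noise null.
#' Terms are evaluated in log-gamma space so large `m` (thousands of
#' ordinates) does not overflow; the alternating series is summed while
#' its terms decrease in magnitude, and in the regime where they grow
#' (deep in the p close to 1 range, where the series is numerically
#' unstable but the decision at any practical level is unaffected) the
#' result is clipped to `[0, 1]`.
#'
#' @param g observed statistic, max ordinate / sum of ordinates.
#' @param m number of ordinates in play.
#' @return The p-value in `[0, 1]`.
#' @export
fisher_g_pvalue <- function(g, m) {
  if (g <= 0) return(1)
  if (g >= 1) return(0)
  jmax <- min(floor(1 / g), m)
  total <- 0
  prev <- Inf
  for (j in seq_len(jmax)) {
    one_minus <- 1 - j * g
    if (one_minus <= 0) break
    logT <- lchoose(m, j) + (m - 1) * log(one_minus)
    term <- exp(logT)
    if (term > prev) break  # series no longer alternating-decreasing
    total <- total + if (j %% 2 == 1) term else -term
    if (term < 1e-16 * max(abs(total), 1)) break
    prev <- term
  }
  min(max(total, 0), 1)
}

#' Fisher's g-test for the largest periodogram ordinate
#'
#' Tests the hypothesis that the series is Gaussian white noise against a
#' hidden periodicity, using \eqn{g = \max_j I(\omega_j) / \sum_j
#' I(\omega_j)}. With `exclude_ranks = r`, the `r` largest ordinates are
#' removed first and the test applies to the next largest among the
#' remaining `m` ordinates (the ingredient of the sequential Whittle
#' test).
#'
#' @param pgram a [periodogram()].
#' @param exclude_ranks number of top-ranked ordinates to remove before
#'   testing (default 0 = plain Fisher test).
#' @return An object of class `periodicity_test` with fields `omega`,
#'   `period_days`, `rank`, `g`, `m`, `p_value`.
#' @export
fisher_gtest <- function(pgram, exclude_ranks = 0L) {
  stopifnot(inherits(pgram, "periodogram"))
  # ties broken towards the lower frequency
  ord <- order(-pgram$ordinate, pgram$omega)
  keep <- ord[-seq_len(exclude_ranks)]
  if (exclude_ranks == 0) keep <- ord
  m <- length(keep)
  if (m < 2) stop("fewer than 2 ordinates remain (m = ", m, ")")
  top <- keep[1]
  g <- pgram$ordinate[top] / sum(pgram$ordinate[keep])
  structure(list(omega = pgram$omega[top],
                 period_days = 2 * pi / pgram$omega[top],
                 rank = exclude_ranks + 1L, g = g, m = m,
                 p_value = fisher_g_pvalue(g, m)),
            class = "periodicity_test")
}

#' @export
print.periodicity_test <- function(x, ...) {
  cat(sprintf(paste0("<periodicity_test> rank %d: period %.3f days, ",
                     "g = %.4g (m = %d), p = %.4g\n"),
              x$rank, x$period_days, x$g, x$m, x$p_value))
  invisible(x)
}

#' Sequential Whittle test of successive periodogram peaks
#'
#' Tests the r-th largest ordinate (r = 1, 2, ...) by applying Fisher's
#' statistic with the r-1 larger ordinates removed and `m` reduced
#' accordingly, stopping at the first non-significant rank or after
#' `max_peaks` tests. Ties between equal ordinates are broken towards the
#' lower frequency.
#'
#' @param pgram a [periodogram()].
#' @param max_peaks maximum number of ranks to test (>= 1).
#' @param alpha significance level for continuing the sequence.
#' @return List of `periodicity_test` objects, one per rank tested.
#' @export
whittle_sequential_test <- function(pgram, max_peaks = 10L, alpha = 0.05) {
  stopifnot(inherits(pgram, "periodogram"))
  if (max_peaks < 1) stop("'max_peaks' must be >= 1")
  out <- list()
  for (r in seq_len(max_peaks)) {
    if (length(pgram$ordinate) - (r - 1) < 2) break
    test <- fisher_gtest(pgram, exclude_ranks = r - 1L)
    out[[r]] <- test
    if (test$p_value > alpha) break
  }
  out
}

#' Ordered set of angular frequencies
#'
#' @param omega numeric vector of distinct angular frequencies in
#'   (0, pi), rad/day.
#' @param snapped optional logical vector marking frequencies snapped to a
#'   nominal cycle.
#' @return An object of class `frequency_set`.
#' @export
frequency_set <- function(omega, snapped = rep(NA, length(omega))) {
  omega <- as.numeric(omega)
  if (any(omega <= 0 | omega >= pi)) stop("frequencies must be in (0, pi)")
  if (anyDuplicated(omega)) stop("frequencies must be distinct")
  o <- order(omega)
  structure(list(omega = omega[o], period_days = 2 * pi / omega[o],
                 snapped = snapped[o]),
            class = "frequency_set")
}

#' Nominal cycle frequencies of the fire-count model
#'
#' The annual cycle and its first three harmonics plus the weekly and
#' half-weekly cycles: `2*pi/365 * (1:4)`, `2*pi/7`, `4*pi/7`.
#'
#' @return A [frequency_set()] of the six nominal frequencies.
#' @export
nominal_frequencies <- function() {
  frequency_set(c(2 * pi / 365 * (1:4), 2 * pi / 7, 4 * pi / 7),
                snapped = rep(TRUE, 6))
}

#' @export
print.frequency_set <- function(x, ...) {
  cat(sprintf("<frequency_set> %d frequencies; periods (days): %s\n",
              length(x$omega),
              paste(sprintf("%.3f", x$period_days), collapse = ", ")))
  invisible(x)
}

#' @export
length.frequency_set <- function(x) length(x$omega)

#' De-seasonalize by harmonic regression
#'
#' Fits ordinary least squares of the series on an intercept, a linear
#' trend and cosine/sine pairs at the given frequencies, and returns the
#' coefficients and the residual series. With an empty frequency set the
#' residuals are simply the detrended, demeaned series.
#'
#' @param series a [log_counts()].
#' @param freqs a [frequency_set()] (possibly empty).
#' @return List with `coefficients` (named vector), `fitted` and
#'   `residuals` (a [log_counts()] on the same time base).
#' @export
harmonic_deseasonalize <- function(series, freqs) {
  stopifnot(inherits(series, "log_counts"))
  omega <- if (inherits(freqs, "frequency_set")) freqs$omega else
    as.numeric(freqs)
  if (anyDuplicated(omega)) stop("duplicated frequency in 'freqs'")
  y <- series$values
  n <- length(y)
  if (n <= 2 * length(omega) + 2)
    stop("series too short for ", length(omega), " frequencies")
  X <- build_design(n, omega)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear harmonic design (frequencies too close for n = ",
         n, ")")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  list(coefficients = beta, fitted = fitted,
       residuals = log_counts(y - fitted, series$start_date,
                              paste0(series$label, " (deseasonalized)")))
}

#' Detect significant periodicities in a log count series
#'
#' Iterative spectral screening: compute the periodogram, run the
#' sequential Whittle test at level `alpha`, collect the significant
#' Fourier frequencies, de-seasonalize the series at the collected
#' frequencies, and repeat (strong seasonal cycles otherwise mask the
#' weaker weekly peaks). Detected Fourier frequencies within one Fourier
#' bin (`2*pi/n`) of a nominal cycle frequency (annual, its first three
#' harmonics, weekly, half-weekly) are snapped to the nominal value for
#' reporting.
#'
#' @param series a [log_counts()].
#' @param alpha significance level (default 0.01).
#' @param candidate_rounds maximum de-seasonalize/re-test rounds.
#' @param max_peaks maximum ranks tested per round.
#' @param snap_to nominal frequencies to snap to, or `NULL` to disable
#'   snapping.
#' @return A [frequency_set()] of the detected (snapped) frequencies,
#'   empty if none are significant.
#' @export
detect_cycles <- function(series, alpha = 0.01, candidate_rounds = 2L,
                          max_peaks = 12L, snap_to = nominal_frequencies()) {
  stopifnot(inherits(series, "log_counts"))
  n <- length(series$values)
  bin <- 2 * pi / n
  nominal <- if (is.null(snap_to)) numeric(0) else snap_to$omega
  collected <- numeric(0)
  snapped <- logical(0)
  work <- series
  for (round in seq_len(candidate_rounds)) {
    pg <- periodogram(work)
    tests <- whittle_sequential_test(pg, max_peaks = max_peaks,
                                     alpha = alpha)
    sig <- vapply(tests, function(t) t$p_value <= alpha, logical(1))
    if (!any(sig)) break
    new <- vapply(tests[sig], function(t) t$omega, numeric(1))
    for (w in new) {
      d <- abs(nominal - w)
      if (length(d) > 0 && min(d) < bin) {
        w_s <- nominal[which.min(d)]; s <- TRUE
      } else {
        w_s <- w; s <- FALSE
      }
      if (all(abs(collected - w_s) > bin / 2)) {
        collected <- c(collected, w_s)
        snapped <- c(snapped, s)
      }
    }
    work <- harmonic_deseasonalize(series, collected)$residuals
  }
  if (length(collected) == 0)
    return(structure(list(omega = numeric(0), period_days = numeric(0),
                          snapped = logical(0)),
                     class = "frequency_set"))
  frequency_set(collected, snapped)
}

#' Sample autocorrelation and partial autocorrelation
#'
#' Standard biased-denominator sample ACF, with the PACF obtained from it
#' by the Durbin-Levinson recursion.
#'
#' @param series a [log_counts()] or numeric vector.
#' @param max_lag maximum lag (< n/2).
#' @return List with `acf` (lags 0..max_lag) and `pacf` (lags
#'   1..max_lag).
#' @export
sample_acf_pacf <- function(series, max_lag) {
  y <- if (inherits(series, "log_counts")) series$values else
    as.numeric(series)
  n <- length(y)
  if (max_lag >= n / 2) stop("'max_lag' must be < n/2")
  rho <- drop(stats::acf(y, lag.max = max_lag, plot = FALSE,
                         demean = TRUE)$acf)
  # Durbin-Levinson: phi[k,k] is the lag-k partial autocorrelation
  pacf <- numeric(max_lag)
  phi_prev <- numeric(0)
  for (k in seq_len(max_lag)) {
    if (k == 1) {
      phi_k <- rho[2]
    } else {
      num <- rho[k + 1] - sum(phi_prev * rho[k:2])
      den <- 1 - sum(phi_prev * rho[2:k])
      phi_k <- num / den
    }
    pacf[k] <- phi_k
    phi_prev <- if (k == 1) phi_k else
      c(phi_prev - phi_k * rev(phi_prev), phi_k)
  }
  list(acf = rho, pacf = pacf)
}

#' Export a periodogram or test list to CSV
#'
#' @param pgram a [periodogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_periodogram_csv <- function(pgram, path) {
  utils::write.csv(
    data.frame(j = pgram$index, omega = pgram$omega,
               period_days = 2 * pi / pgram$omega,
               ordinate = pgram$ordinate),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_periodogram_csv
#' @param tests list of `periodicity_test` objects (from
#'   [whittle_sequential_test()]).
#' @export
write_tests_csv <- function(tests, path) {
  utils::write.csv(
    data.frame(rank = vapply(tests, `[[`, 0L, "rank"),
               period_days = vapply(tests, `[[`, 0, "period_days"),
               g = vapply(tests, `[[`, 0, "g"),
               m = vapply(tests, `[[`, 0L, "m"),
               p = vapply(tests, `[[`, 0, "p_value")),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
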