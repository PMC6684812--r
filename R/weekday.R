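#' Partition a mean-function posterior by weekday
#'
#' Splits the posterior of \eqn{M_t} over a window of whole weeks into the
#' seven interleaved weekday sub-series \eqn{t_i = i, i+7, i+14, \dots}
#' (1 = Monday ... 7 = Sunday): per-weekday mean sub-vectors, covariance
#' sub-matrices, cross-covariances with Sunday, and the matching segments
#' of a simultaneous credible band built on the same window.
#'
#' @param mfp a [mean_function_posterior()] whose window length is
#'   divisible by 7.
#' @param band a [simultaneous_band()] built on the same window.
#' @param start_weekday ISO weekday of the first window position
#'   (default 1 = Monday).
#' @return An object of class `weekday_partition` with list fields
#'   `indices`, `means`, `covs`, `cross_sunday`, `band_lower`,
#'   `band_upper` (each of length 7, Monday first), plus `weeks`,
#'   `start_date` and `label`.
#' @export
partition_by_weekday <- function(mfp, band, start_weekday = 1L) {
  stopifnot(inherits(mfp, "mean_fn_posterior"))
  n <- length(mfp$t)
  if (n %% 7 != 0) stop("window length must be divisible by 7")
  if (length(band$mean) != n || !all(band$t == mfp$t))
    stop("band and posterior windows do not match")
  pos_weekday <- ((start_weekday - 1L + seq_len(n) - 1L) %% 7L) + 1L
  indices <- lapply(1:7, function(i) which(pos_weekday == i))
  sunday <- indices[[7]]
  structure(list(
    indices = indices,
    means = lapply(indices, function(ix) mfp$mean[ix]),
    covs = lapply(indices, function(ix) mfp$cov[ix, ix, drop = FALSE]),
    cross_sunday = lapply(indices, function(ix)
      mfp$cov[ix, sunday, drop = FALSE]),
    band_lower = lapply(indices, function(ix) band$lower[ix]),
    band_upper = lapply(indices, function(ix) band$upper[ix]),
    weeks = n %/% 7L,
    start_date = mfp$start_date, label = mfp$label),
    class = "weekday_partition")
}

#' @export
print.weekday_partition <- function(x, ...) {
  cat(sprintf("<weekday_partition> '%s': %d weeks x 7 weekdays\n",
              x$label, x$weeks))
  invisible(x)
}

weekday_table_df <- function(estimates, kind, reference = 7L) {
  df <- data.frame(weekday = 1:7, day = weekday_names(),
                   estimate = vapply(estimates, `[[`, 0, "estimate"),
                   mc_error = vapply(estimates, `[[`, 0, "se"))
  attr(df, "kind") <- kind
  attr(df, "reference") <- reference
  class(df) <- c("weekday_table", "data.frame")
  df
}

#' Band-membership probabilities per weekday
#'
#' For each weekday i, the posterior probability that the weekday's
#' mean-function sub-vector lies entirely inside the Sunday segment of
#' the simultaneous credible band, week by week:
#' \eqn{P(LB_{t_7} \le M_{t_i} \le UB_{t_7})}. Small values for a weekday
#' mean its fire level is incompatible with Sunday's; Sunday's own entry
#' exceeds the joint band level because a sub-vector is easier to contain
#' than the full vector.
#'
#' @param partition a [partition_by_weekday()] result.
#' @param n_mc Monte-Carlo sample size per weekday.
#' @param seed integer seed.
#' @return A `weekday_table` data frame with columns `weekday`, `day`,
#'   `estimate`, `mc_error`.
#' @export
membership_table <- function(partition, n_mc = 100000L, seed = 1L) {
  stopifnot(inherits(partition, "weekday_partition"))
  lb <- partition$band_lower[[7]]
  ub <- partition$band_upper[[7]]
  est <- lapply(1:7, function(i) {
    interval_probability(partition$means[[i]], partition$covs[[i]],
                         lb, ub, n_mc = n_mc, seed = seed + i)
  })
  weekday_table_df(est, "membership")
}

#' Exceedance probabilities per weekday
#'
#' For each weekday i, the posterior probability that the weekday's
#' mean-function sub-vector lies entirely above Sunday's estimated
#' (posterior-mean) function, week by week:
#' \eqn{P(M_{t_i} > \hat M_{t_7})}. The threshold is the fixed Sunday
#' posterior-mean vector; the inequality is strict.
#'
#' @inheritParams membership_table
#' @return A `weekday_table` data frame.
#' @export
exceedance_table <- function(partition, n_mc = 100000L, seed = 1L) {
  stopifnot(inherits(partition, "weekday_partition"))
  thr <- partition$means[[7]]
  est <- lapply(1:7, function(i) {
    exceedance_probability(partition$means[[i]], partition$covs[[i]],
                           thr, n_mc = n_mc, seed = seed + i)
  })
  weekday_table_df(est, "exceedance")
}

#' @export
print.weekday_table <- function(x, ...) {
  cat(sprintf("<weekday_table> %s probabilities vs %s:\n",
              attr(x, "kind"), weekday_names()[attr(x, "reference")]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Locate the window of strongest weekly cycle
#'
#' For each week w counts the weekdays (Monday-Saturday) whose estimated
#' mean exceeds the Sunday upper band bound in that week,
#' \eqn{n_w = \#\{i \le 6 : \hat M_{t_i}(w) > UB_{t_7}(w)\}}, and reports
#' the longest run of consecutive weeks with `n_w >= threshold_days`
#' (earliest run on ties) together with the full weekly profile.
#'
#' @param partition a [partition_by_weekday()] result.
#' @param threshold_days minimum number of exceeding weekdays for a week
#'   to qualify (1-6).
#' @return An object of class `cycle_window` with fields `profile`
#'   (per-week counts), `threshold_days`, `start_week`, `end_week`,
#'   `length`, `start_date`, `end_date` (calendar dates of the run, `NA`
#'   if no week qualifies).
#' @export
strongest_cycle_window <- function(partition, threshold_days = 1L) {
  stopifnot(inherits(partition, "weekday_partition"))
  if (threshold_days < 1 || threshold_days > 6)
    stop("'threshold_days' must be in 1..6")
  weeks <- partition$weeks
  ub7 <- partition$band_upper[[7]]
  profile <- integer(weeks)
  for (i in 1:6)
    profile <- profile + as.integer(partition$means[[i]] > ub7)
  qual <- profile >= threshold_days
  best_len <- 0L; best_start <- NA_integer_
  run_start <- NA_integer_
  for (w in seq_len(weeks)) {
    if (qual[w]) {
      if (is.na(run_start)) run_start <- w
      len <- w - run_start + 1L
      if (len > best_len) { best_len <- len; best_start <- run_start }
    } else {
      run_start <- NA_integer_
    }
  }
  start_week <- best_start
  end_week <- if (best_len > 0) best_start + best_len - 1L else
    NA_integer_
  sd <- partition$start_date
  structure(list(profile = profile, threshold_days = threshold_days,
                 start_week = start_week, end_week = end_week,
                 length = best_len,
                 start_date = if (best_len > 0)
                   sd + (start_week - 1L) * 7L else as.Date(NA),
                 end_date = if (best_len > 0)
                   sd + end_week * 7L - 1L else as.Date(NA),
                 label = partition$label),
            class = "cycle_window")
}

#' @export
print.cycle_window <- function(x, ...) {
  if (x$length == 0) {
    cat("<cycle_window> no week qualifies (all profile counts below",
        x$threshold_days, ")\n")
  } else {
    cat(sprintf(paste0("<cycle_window> weeks %d-%d (%d weeks, %s to %s), ",
                       ">= %d weekday(s) above Sunday's upper band\n"),
                x$start_week, x$end_week, x$length,
                format(x$start_date), format(x$end_date),
                x$threshold_days))
  }
  invisible(x)
}

#' Anthrome share table
#'
#' Counts labelled fire records per anthrome group and their percentage
#' of the labelled total (rounded to 2 decimals).
#'
#' @param x a labelled [fire_records()] data frame, or a named numeric
#'   vector of per-group counts.
#' @param groups group names defining the table order.
#' @return Data frame with columns `group`, `fires`, `percent`.
#' @export
anthrome_share_table <- function(x, groups = anthrome_groups()) {
  if (inherits(x, "fire_records") || is.data.frame(x)) {
    counts <- vapply(groups, function(g)
      sum(x$anthrome_group == g, na.rm = TRUE), numeric(1))
  } else {
    counts <- as.numeric(x[groups])
    counts[is.na(counts)] <- 0
    names(counts) <- groups
  }
  total <- sum(counts)
  if (total == 0) stop("no labelled records in any group")
  data.frame(group = groups, fires = unname(counts),
             percent = round(100 * unname(counts) / total, 2),
             row.names = NULL)
}
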