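#' Daily count series
#'
#' Container for an ordered series of non-negative daily counts starting at
#' a given calendar date. Day `t` of the series corresponds to
#' `start_date + (t - 1)`; weekdays follow the ISO convention
#' (1 = Monday ... 7 = Sunday) of the proleptic Gregorian calendar.
#'
#' @param counts integer vector of non-negative counts, one per consecutive
#'   calendar day.
#' @param start_date `Date` (or string coercible to one) of the first count.
#' @param label short text label for the series (e.g. `"global"`,
#'   `"Croplands"`).
#' @return An object of class `daily_counts` with fields `counts`,
#'   `start_date` and `label`.
#' @export
daily_counts <- function(counts, start_date, label = "series") {
  start_date <- as.Date(start_date)
  if (length(start_date) != 1L || is.na(start_date))
    stop("'start_date' must be a single valid date")
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("'counts' must have length >= 1")
  if (anyNA(counts) || any(counts < 0))
    stop("'counts' must be non-negative and non-missing")
  structure(list(counts = counts, start_date = start_date,
                 label = as.character(label)),
            class = "daily_counts")
}

#' Log-scale daily series
#'
#' Container for the log-transformed counts \eqn{Y_t}, the response of the
#' harmonic-regression model.
#'
#' @param values finite numeric vector, one value per consecutive day.
#' @param start_date `Date` of the first value.
#' @param label short text label.
#' @return An object of class `log_counts`.
#' @export
log_counts <- function(values, start_date, label = "series") {
  start_date <- as.Date(start_date)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("'values' must have length >= 1")
  if (!all(is.finite(values))) stop("'values' must all be finite")
  structure(list(values = values, start_date = start_date,
                 label = as.character(label)),
            class = "log_counts")
}

#' @export
print.daily_counts <- function(x, ...) {
  cat(sprintf("<daily_counts> '%s': %d days from %s (total %s)\n",
              x$label, length(x$counts), format(x$start_date),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
print.log_counts <- function(x, ...) {
  cat(sprintf("<log_counts> '%s': %d days from %s (mean %.4f, sd %.4f)\n",
              x$label, length(x$values), format(x$start_date),
              mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' @export
length.daily_counts <- function(x) length(x$counts)

#' @export
length.log_counts <- function(x) length(x$values)

# ISO weekday: 1 = Monday ... 7 = Sunday
iso_weekday <- function(date) {
  as.integer(format(as.Date(date), "%u"))
}

series_dates <- function(series) {
  n <- if (inherits(series, "daily_counts")) length(series$counts)
       else length(series$values)
  seq(series$start_date, by = "day", length.out = n)
}

weekday_names <- function() {
  c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday", "Saturday",
    "Sunday")
}

#' Write a daily series to CSV
#'
#' Writes a two-column CSV (`date`, `count` or `value`) readable by any
#' spreadsheet or data tool.
#'
#' @param series a `daily_counts` or `log_counts` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  dates <- series_dates(series)
  if (inherits(series, "daily_counts")) {
    df <- data.frame(date = format(dates), count = series$counts)
  } else {
    df <- data.frame(date = format(dates), value = series$values)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
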