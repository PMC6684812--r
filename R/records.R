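#' Active-fire record set
#'
#' A data frame of individual satellite active-fire detections in the
#' MCD14ML dialect: acquisition date and time, satellite (T = Terra,
#' A = Aqua), coordinates, detection confidence (0-100) and type code
#' (0 = presumed vegetation fire, 1 = active volcano, 2 = other static
#' land source, 3 = offshore). Optional columns `anthrome_code` and
#' `anthrome_group` are filled by [assign_anthromes()].
#'
#' @param acq_date `Date` vector.
#' @param acq_time integer minutes of day (0-1439).
#' @param satellite character, `"T"` or `"A"`.
#' @param lat,lon coordinates in degrees.
#' @param confidence integer 0-100.
#' @param type integer type code 0-3.
#' @param anthrome_code,anthrome_group optional label columns.
#' @return A data frame of class `fire_records`.
#' @export
fire_records <- function(acq_date, acq_time, satellite, lat, lon,
                         confidence, type,
                         anthrome_code = NA_integer_,
                         anthrome_group = NA_character_) {
  df <- data.frame(acq_date = as.Date(acq_date),
                   acq_time = as.integer(acq_time),
                   satellite = as.character(satellite),
                   lat = as.numeric(lat), lon = as.numeric(lon),
                   confidence = as.integer(confidence),
                   type = as.integer(type),
                   anthrome_code = as.integer(anthrome_code),
                   anthrome_group = as.character(anthrome_group),
                   stringsAsFactors = FALSE)
  if (any(df$lat < -90 | df$lat > 90, na.rm = TRUE) ||
      any(df$lon < -180 | df$lon > 180, na.rm = TRUE))
    stop("coordinates out of range")
  if (any(df$confidence < 0 | df$confidence > 100, na.rm = TRUE))
    stop("confidence out of range 0-100")
  class(df) <- c("fire_records", "data.frame")
  df
}

empty_fire_records <- function() {
  fire_records(as.Date(character(0)), integer(0), character(0),
               numeric(0), numeric(0), integer(0), integer(0))
}

#' Read MCD14ML-style fire records
#'
#' Parses delimited text (whitespace- or comma-separated) with columns
#' `YYYYMMDD HHMM sat lat lon T21 T31 sample FRP conf type`; a header line
#' is detected and tolerated, and the brightness/sample/FRP columns are
#' read but ignored. Malformed lines and records with out-of-range
#' coordinates are dropped and counted (see attribute `"dropped"`).
#'
#' @param path file path.
#' @param quiet suppress the drop-count message.
#' @return A [fire_records()] data frame with attribute `dropped`, a list
#'   with counts `malformed` and `out_of_range`.
#' @export
read_mcd14ml <- function(path, quiet = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_fire_records())
  sep_split <- function(x) {
    if (grepl(",", x)) trimws(strsplit(x, ",")[[1]])
    else strsplit(trimws(x), "\\s+")[[1]]
  }
  required <- c("YYYYMMDD", "HHMM", "sat", "lat", "lon", "conf", "type")
  first <- sep_split(lines[1])
  has_header <- suppressWarnings(is.na(as.numeric(first[1])))
  if (has_header) {
    norm <- tolower(gsub("[^A-Za-z0-9]", "", first))
    alias <- list(YYYYMMDD = c("yyyymmdd", "acqdate", "date"),
                  HHMM = c("hhmm", "acqtime", "time"),
                  sat = c("sat", "satellite"),
                  lat = c("lat", "latitude"),
                  lon = c("lon", "long", "longitude"),
                  conf = c("conf", "confidence"),
                  type = c("type", "typecode"))
    idx <- vapply(required, function(k) {
      m <- which(norm %in% alias[[k]])
      if (length(m) == 0) NA_integer_ else m[1]
    }, integer(1))
    if (anyNA(idx))
      stop("missing required column(s): ",
           paste(required[is.na(idx)], collapse = ", "))
    lines <- lines[-1]
  } else {
    # positional layout: YYYYMMDD HHMM sat lat lon T21 T31 sample FRP conf type
    idx <- c(YYYYMMDD = 1L, HHMM = 2L, sat = 3L, lat = 4L, lon = 5L,
             conf = 10L, type = 11L)
  }
  n_malformed <- 0L
  n_range <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- sep_split(lines[i])
    if (length(f) < max(idx)) { n_malformed <- n_malformed + 1L; next }
    date <- as.Date(f[idx["YYYYMMDD"]], format = "%Y%m%d")
    hhmm <- suppressWarnings(as.integer(f[idx["HHMM"]]))
    lat <- suppressWarnings(as.numeric(f[idx["lat"]]))
    lon <- suppressWarnings(as.numeric(f[idx["lon"]]))
    conf <- suppressWarnings(as.integer(f[idx["conf"]]))
    type <- suppressWarnings(as.integer(f[idx["type"]]))
    if (is.na(date) || is.na(hhmm) || is.na(lat) || is.na(lon) ||
        is.na(conf) || is.na(type)) {
      n_malformed <- n_malformed + 1L; next
    }
    if (lat < -90 || lat > 90 || lon < -180 || lon > 180) {
      n_range <- n_range + 1L; next
    }
    rows[[i]] <- list(date = date, time = (hhmm %/% 100L) * 60L + hhmm %% 100L,
                      sat = f[idx["sat"]], lat = lat, lon = lon,
                      conf = conf, type = type)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    rec <- empty_fire_records()
  } else {
    rec <- fire_records(
      acq_date = as.Date(vapply(rows, function(r) as.character(r$date),
                                character(1))),
      acq_time = vapply(rows, function(r) r$time, integer(1)),
      satellite = vapply(rows, function(r) r$sat, character(1)),
      lat = vapply(rows, function(r) r$lat, numeric(1)),
      lon = vapply(rows, function(r) r$lon, numeric(1)),
      confidence = vapply(rows, function(r) r$conf, integer(1)),
      type = vapply(rows, function(r) r$type, integer(1)))
  }
  attr(rec, "dropped") <- list(malformed = n_malformed,
                               out_of_range = n_range)
  if (!quiet && (n_malformed > 0 || n_range > 0))
    message("read_mcd14ml: dropped ", n_malformed, " malformed and ",
            n_range, " out-of-range record(s)")
  rec
}

#' Write fire records in the MCD14ML dialect
#'
#' Writes the space-separated positional layout read by [read_mcd14ml()];
#' the unused brightness/sample/FRP columns are filled with nominal values.
#'
#' @param records a [fire_records()] data frame.
#' @param path output file path.
#' @param header write a header line.
#' @return `path`, invisibly.
#' @export
write_mcd14ml <- function(records, path, header = TRUE) {
  lines <- sprintf("%s %04d %s %.6f %.6f 310.0 290.0 500 20.0 %d %d",
                   format(records$acq_date, "%Y%m%d"),
                   (records$acq_time %/% 60L) * 100L +
                     records$acq_time %% 60L,
                   records$satellite, records$lat, records$lon,
                   records$confidence, records$type)
  if (header)
    lines <- c("YYYYMMDD HHMM sat lat lon T21 T31 sample FRP conf type",
               lines)
  writeLines(lines, path)
  invisible(path)
}

#' Screen fire records by type and confidence
#'
#' Retains records whose type code is in `keep_types` and whose detection
#' confidence is at least `min_confidence`, preserving order. The default
#' keeps presumed vegetation fires (type 0) at any confidence.
#'
#' @param records a [fire_records()] data frame.
#' @param min_confidence minimum confidence (0-100).
#' @param keep_types integer vector of type codes to retain.
#' @return The filtered [fire_records()].
#' @export
screen_records <- function(records, min_confidence = 0, keep_types = 0L) {
  keep <- records$type %in% keep_types &
    records$confidence >= min_confidence
  out <- records[keep, , drop = FALSE]
  class(out) <- c("fire_records", "data.frame")
  out
}

#' Label fire records with anthrome classes
#'
#' Looks up the grid cell containing each record by the half-open floor
#' rule (cell row = `floor((ytop - lat)/cellsize)`, col =
#' `floor((lon - xll)/cellsize)`; points on shared edges belong to the
#' cell south/east of the edge) and attaches the cell's code and its
#' aggregate group. Records over nodata or outside the grid stay
#' unlabeled but are retained.
#'
#' @param records a [fire_records()] data frame.
#' @param grid an [anthrome_grid()].
#' @param mapping named vector mapping code (as name) to group; every code
#'   present in the grid must be covered.
#' @return The labelled [fire_records()].
#' @export
assign_anthromes <- function(records, grid,
                             mapping = default_anthrome_mapping()) {
  stopifnot(inherits(grid, "anthrome_grid"))
  present <- setdiff(unique(as.vector(grid$codes)), grid$nodata)
  unmapped <- setdiff(present, as.integer(names(mapping)))
  if (length(unmapped) > 0)
    stop("anthrome mapping is missing grid code(s): ",
         paste(sort(unmapped), collapse = ", "))
  if (nrow(records) == 0) return(records)
  cell <- grid_cell_of(grid, records$lat, records$lon)
  code <- rep(NA_integer_, nrow(records))
  inside <- !is.na(cell$row)
  code[inside] <- grid$codes[cbind(cell$row[inside], cell$col[inside])]
  code[!is.na(code) & code == grid$nodata] <- NA_integer_
  records$anthrome_code <- code
  records$anthrome_group <- ifelse(is.na(code), NA_character_,
                                   unname(mapping[as.character(code)]))
  records
}

#' Aggregate fire records to daily counts
#'
#' Counts records per calendar day over an inclusive window, with zero
#' counts for empty days; optionally one series per anthrome group
#' (unlabeled records form an `"Unlabeled"` series), so that group counts
#' plus unlabeled counts sum to the total on every day.
#'
#' @param records a [fire_records()] data frame.
#' @param start_date,end_date window bounds (inclusive).
#' @param group_by `"none"` for a single series, `"anthrome_group"` for a
#'   list of series per group.
#' @return A [daily_counts()] (`group_by = "none"`) or a named list of
#'   them.
#' @export
aggregate_daily <- function(records, start_date, end_date,
                            group_by = c("none", "anthrome_group")) {
  group_by <- match.arg(group_by)
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (start_date > end_date) stop("'start_date' must be <= 'end_date'")
  days <- seq(start_date, end_date, by = "day")
  tab_one <- function(rec, label) {
    idx <- match(rec$acq_date, days)
    idx <- idx[!is.na(idx)]
    counts <- tabulate(idx, nbins = length(days))
    daily_counts(counts, start_date, label)
  }
  if (group_by == "none") return(tab_one(records, "all"))
  grp <- records$anthrome_group
  grp[is.na(grp)] <- "Unlabeled"
  labels <- sort(unique(grp))
  out <- stats::setNames(lapply(labels, function(g) {
    tab_one(records[grp == g, , drop = FALSE], g)
  }), labels)
  out
}

#' Trim a daily series to full Monday-Sunday weeks
#'
#' Removes leading days before the first Monday and trailing days after
#' the last Sunday, so the result starts on a Monday and has length
#' divisible by 7.
#'
#' @param series a [daily_counts()] or [log_counts()].
#' @return The trimmed series, same class.
#' @export
trim_to_full_weeks <- function(series) {
  dates <- series_dates(series)
  n <- length(dates)
  if (n < 7) stop("series shorter than one week")
  wd <- iso_weekday(dates)
  first <- which(wd == 1L)[1]
  last <- max(which(wd == 7L))
  if (is.na(first) || length(last) == 0 || last < first ||
      last - first + 1 < 7)
    stop("fewer than 7 days remain after trimming to full weeks")
  if (inherits(series, "daily_counts")) {
    daily_counts(series$counts[first:last], dates[first], series$label)
  } else {
    log_counts(series$values[first:last], dates[first], series$label)
  }
}

#' Count complete Monday-Sunday weeks in a date range
#'
#' @param start_date,end_date inclusive range bounds.
#' @return Integer number of Monday-to-Sunday weeks wholly inside the
#'   range.
#' @examples
#' count_full_weeks("2002-07-08", "2012-07-29")  # 525
#' @export
count_full_weeks <- function(start_date, end_date) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (start_date > end_date) stop("'start_date' must be <= 'end_date'")
  first_monday <- start_date + (8L - iso_weekday(start_date)) %% 7L
  last_sunday <- end_date - (iso_weekday(end_date)) %% 7L
  if (last_sunday < first_monday + 6L) return(0L)
  as.integer((as.integer(last_sunday - first_monday) + 1L) %/% 7L)
}

#' Per-weekday mean and standard deviation of a trimmed series
#'
#' For a series trimmed to full weeks, returns the mean and sample
#' standard deviation of the counts falling on each weekday, Monday first.
#'
#' @param series a [daily_counts()] starting on a Monday with length
#'   divisible by 7.
#' @return Data frame with columns `weekday` (1-7), `day`, `mean`, `sd`.
#' @export
weekday_summary <- function(series) {
  stopifnot(inherits(series, "daily_counts"))
  n <- length(series$counts)
  if (n %% 7 != 0 || iso_weekday(series$start_date) != 1L)
    stop("series must be trimmed to full weeks (see trim_to_full_weeks)")
  m <- matrix(series$counts, ncol = 7, byrow = TRUE)
  data.frame(weekday = 1:7, day = weekday_names(),
             mean = colMeans(m), sd = apply(m, 2, stats::sd))
}

#' Spatially gridded summaries of fire records
#'
#' Tallies records on a regular lat/lon grid (default 0.5 degrees,
#' global). Statistics: `"count"` = records per cell; `"min_weekday"` =
#' the weekday (1 = Monday ... 7 = Sunday) with the fewest records among
#' weekdays having at least one record (ties broken towards the smaller
#' index); `"modal_anthrome"` = the most frequent anthrome code among the
#' cell's records (ties towards the smaller code). Cells with no records
#' are omitted.
#'
#' @param records a [fire_records()] data frame (labelled, for
#'   `"modal_anthrome"`).
#' @param cellsize cell size in degrees.
#' @param window optional `c(start, end)` date window (inclusive).
#' @param statistic one of `"count"`, `"min_weekday"`,
#'   `"modal_anthrome"`.
#' @return Data frame with columns `row`, `col`, `lon_center`,
#'   `lat_center`, `value`.
#' @export
grid_summary <- function(records, cellsize = 0.5, window = NULL,
                         statistic = c("count", "min_weekday",
                                       "modal_anthrome")) {
  statistic <- match.arg(statistic)
  if (!is.null(window)) {
    window <- as.Date(window)
    keep <- records$acq_date >= window[1] & records$acq_date <= window[2]
    records <- records[keep, , drop = FALSE]
  }
  if (statistic == "modal_anthrome" && all(is.na(records$anthrome_code)))
    stop("'modal_anthrome' requires labelled records (assign_anthromes)")
  nrows <- as.integer(ceiling(180 / cellsize))
  ncols <- as.integer(ceiling(360 / cellsize))
  row <- pmin(pmax(floor((90 - records$lat) / cellsize) + 1, 1), nrows)
  col <- pmin(pmax(floor((records$lon + 180) / cellsize) + 1, 1), ncols)
  key <- (row - 1) * ncols + col
  if (nrow(records) == 0)
    return(data.frame(row = integer(0), col = integer(0),
                      lon_center = numeric(0), lat_center = numeric(0),
                      value = numeric(0)))
  groups <- split(seq_len(nrow(records)), key)
  value <- switch(statistic,
    count = vapply(groups, length, numeric(1)),
    min_weekday = vapply(groups, function(i) {
      wd <- iso_weekday(records$acq_date[i])
      tab <- table(factor(wd, levels = 1:7))
      tab <- tab[tab > 0]
      as.numeric(names(tab)[which.min(tab)])
    }, numeric(1)),
    modal_anthrome = vapply(groups, function(i) {
      code <- records$anthrome_code[i]
      code <- code[!is.na(code)]
      if (length(code) == 0) return(NA_real_)
      tab <- table(code)
      as.numeric(names(tab)[which.max(tab)])
    }, numeric(1)))
  k <- as.integer(names(groups))
  row_out <- (k - 1L) %/% ncols + 1L
  col_out <- (k - 1L) %% ncols + 1L
  out <- data.frame(
    row = row_out, col = col_out,
    lon_center = -180 + (col_out - 0.5) * cellsize,
    lat_center = 90 - (row_out - 0.5) * cellsize,
    value = unname(value))
  out[order(out$row, out$col), , drop = FALSE]
}
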