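toy_lines <- c(
  "YYYYMMDD HHMM sat lat lon T21 T31 sample FRP conf type",
  "20100104 0130 T 10.25 20.75 315.2 290.1 600 25.4 85 0",
  "20100104 1342 A -5.50 -60.25 320.0 295.0 100 40.0 95 0",
  "20100105 0215 T 45.00 5.00 310.0 288.0 300 12.0 40 1")

test_that("MCD14ML reader parses records and fields round-trip", {
  path <- tempfile(); on.exit(unlink(path))
  writeLines(toy_lines, path)
  rec <- read_mcd14ml(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$acq_date[1], as.Date("2010-01-04"))
  expect_equal(rec$acq_time[2], 13L * 60L + 42L)
  expect_equal(rec$satellite, c("T", "A", "T"))
  expect_equal(rec$lat, c(10.25, -5.50, 45.00))
  expect_equal(rec$confidence, c(85L, 95L, 40L))
  expect_equal(rec$type, c(0L, 0L, 1L))
  # headerless and comma-separated dialects parse identically
  path2 <- tempfile(); on.exit(unlink(path2), add = TRUE)
  writeLines(gsub(" +", ",", toy_lines[-1]), path2)
  rec2 <- read_mcd14ml(path2)
  expect_equal(rec2$lat, rec$lat)
  expect_equal(rec2$acq_date, rec$acq_date)
})

test_that("out-of-range and malformed lines are dropped and counted", {
  path <- tempfile(); on.exit(unlink(path))
  writeLines(c(toy_lines,
               "20100106 0100 T 99.0 10.0 310 290 1 1 80 0",
               "not a record at all"), path)
  expect_message(rec <- read_mcd14ml(path), "dropped")
  expect_equal(nrow(rec), 3L)
  expect_equal(attr(rec, "dropped")$out_of_range, 1L)
  expect_equal(attr(rec, "dropped")$malformed, 1L)
})

test_that("a missing required column fails by name", {
  path <- tempfile(); on.exit(unlink(path))
  writeLines(c("YYYYMMDD HHMM sat lat T21 T31 sample FRP conf type",
               "20100104 0130 T 10.25 315.2 290.1 600 25.4 85 0"), path)
  expect_error(read_mcd14ml(path), "lon")
})

test_that("screening filters by type and confidence", {
  rec <- fire_records(rep(as.Date("2010-01-01"), 4), 0L, "T",
                      lat = 1:4, lon = 1:4,
                      confidence = c(10L, 30L, 90L, 50L),
                      type = c(0L, 1L, 2L, 3L))
  expect_equal(nrow(screen_records(rec)), 1L)
  expect_equal(nrow(screen_records(rec, keep_types = 0:3,
                                   min_confidence = 30)), 3L)
  # brute-force predicate scan over a random record set
  set.seed(1)
  big <- fire_records(rep(as.Date("2010-01-01"), 100), 0L, "T",
                      lat = runif(100, -80, 80),
                      lon = runif(100, -170, 170),
                      confidence = sample(0:100, 100, TRUE),
                      type = sample(0:3, 100, TRUE))
  got <- screen_records(big, min_confidence = 40, keep_types = c(0L, 2L))
  want <- which(vapply(seq_len(100), function(i)
    big$type[i] %in% c(0L, 2L) && big$confidence[i] >= 40, logical(1)))
  expect_equal(which(paste(big$lat, big$lon) %in%
                       paste(got$lat, got$lon)), want)
})

test_that("ESRI ASCII grids read, write and round-trip", {
  path <- tempfile(); on.exit(unlink(path))
  writeLines(c("ncols 2", "nrows 2", "xllcorner 10", "yllcorner 40",
               "cellsize 0.5", "NODATA_value -9999",
               "31 41", "51 61"), path)
  g <- read_anthrome_grid(path)
  expect_equal(g$codes, matrix(c(31L, 51L, 41L, 61L), 2, 2))
  expect_equal(g$cellsize, 0.5)

  bad <- tempfile(); on.exit(unlink(bad), add = TRUE)
  writeLines(c("ncols 2", "nrows 2", "xllcorner 10", "yllcorner 40",
               "cellsize 0.5", "NODATA_value -9999",
               "31 41", "51"), bad)
  expect_error(read_anthrome_grid(bad), "row 2")

  toy <- make_toy_anthrome_grid(3, 4, list(
    list(rows = 1:3, cols = 1:2, code = 21),
    list(rows = 1:3, cols = 3:4, code = 52)), cellsize = 0.25,
    xllcorner = -10, yllcorner = -5)
  rt <- tempfile(); on.exit(unlink(rt), add = TRUE)
  write_anthrome_grid(toy, rt)
  back <- read_anthrome_grid(rt)
  expect_equal(back$codes, toy$codes)
  expect_equal(back$xllcorner, toy$xllcorner)
  expect_equal(back$cellsize, toy$cellsize)
})

test_that("anthrome labelling matches the exhaustive rectangle oracle", {
  set.seed(42)
  g <- make_toy_anthrome_grid(5, 7, list(
    list(rows = 1:2, cols = 1:7, code = 31),
    list(rows = 3:4, cols = 1:3, code = 43),
    list(rows = 3:4, cols = 4:7, code = 54),
    list(rows = 5, cols = 1:7, code = 62)), cellsize = 0.5,
    xllcorner = 10, yllcorner = 40)
  # cell-center lookup
  rec <- fire_records(as.Date("2010-01-01"), 0L, "T",
                      lat = 42.25 - 0 * 0.5, lon = 10.25,
                      confidence = 100L, type = 0L)
  expect_equal(assign_anthromes(rec, g)$anthrome_code, 31L)
  # random points incl. some outside the grid and some on edges
  n <- 1000
  lat <- runif(n, 39.5, 43.0)
  lon <- runif(n, 9.5, 14.0)
  edge <- sample(n, 50)
  lat[edge] <- 42.5 - 0.5 * sample(0:5, 50, TRUE)  # exactly on row edges
  recs <- fire_records(rep(as.Date("2010-01-01"), n), 0L, "T",
                       lat = lat, lon = lon,
                       confidence = 100L, type = 0L)
  got <- assign_anthromes(recs, g)$anthrome_code
  want <- brute_force_assign(g, lat, lon)
  expect_equal(got, want)
  # unmapped code in the grid triggers a hard failure listing it
  expect_error(assign_anthromes(recs, g, mapping = c("31" = "Croplands")),
               "43")
})

test_that("daily aggregation covers the window and conserves records", {
  d <- as.Date("2010-03-01")
  rec <- fire_records(c(rep(d, 5), d + 2), 0L, "T",
                      lat = seq(1, 6), lon = seq(1, 6),
                      confidence = 100L, type = 0L)
  one <- aggregate_daily(rec, d, d)
  expect_equal(one$counts, 5)
  s <- aggregate_daily(rec, d, d + 3)
  expect_equal(s$counts, c(5, 0, 1, 0))

  g <- make_toy_anthrome_grid(1, 2, list(
    list(rows = 1, cols = 1, code = 31)), cellsize = 1)
  rec$lat <- rep(0.5, 6); rec$lon <- c(0.5, 0.5, 1.5, 1.5, 0.5, 1.5)
  lab <- assign_anthromes(rec, g)
  per <- aggregate_daily(lab, d, d + 3, group_by = "anthrome_group")
  expect_setequal(names(per), c("Croplands", "Unlabeled"))
  total <- aggregate_daily(lab, d, d + 3)
  expect_equal(per$Croplands$counts + per$Unlabeled$counts,
               total$counts)
})

test_that("week trimming aligns Monday..Sunday", {
  wed <- as.Date("2010-03-03")  # a Wednesday
  s <- daily_counts(1:12, wed)
  t <- trim_to_full_weeks(s)
  expect_equal(length(t$counts), 7L)
  expect_equal(t$start_date, as.Date("2010-03-08"))  # next Monday
  expect_equal(t$counts, 6:12)

  study <- daily_counts(rep(1, 3675), as.Date("2002-07-08"))
  expect_equal(trim_to_full_weeks(study)$counts, study$counts)

  aligned <- daily_counts(1:14, as.Date("2010-03-08"))
  expect_equal(trim_to_full_weeks(aligned), aligned)

  expect_error(trim_to_full_weeks(daily_counts(1:8, wed)), "fewer than")
})

test_that("full-week counting handles the study period and edge cases", {
  expect_equal(count_full_weeks("2002-07-08", "2012-07-29"), 525L)
  expect_equal(count_full_weeks("2002-07-08", "2002-07-14"), 1L)
  expect_equal(count_full_weeks("2002-07-08", "2002-07-13"), 0L)
  # property: k whole weeks from any Monday
  monday <- as.Date("2013-01-07")
  for (k in 1:10)
    expect_equal(count_full_weeks(monday, monday + 7 * k - 1), k)
})

test_that("weekday summaries report per-day mean and sd", {
  s <- daily_counts(rep(10, 21), as.Date("2010-03-08"))
  ws <- weekday_summary(s)
  expect_equal(ws$mean, rep(10, 7))
  expect_equal(ws$sd, rep(0, 7))

  counts <- rep(10, 14); counts[c(7, 14)] <- 5
  ws2 <- weekday_summary(daily_counts(counts, as.Date("2010-03-08")))
  expect_equal(ws2$mean[7], 5)
  expect_equal(ws2$sd[7], 0)
  expect_equal(ws2$day[7], "Sunday")

  # synthetic Sunday deficit: Sunday mean is the weekly minimum
  spec <- flat_spec(n_days = 3675, a0 = log(200), sd = 1e-12,
                    weekday_offsets = c(rep(0, 6), -0.10),
                    count_mode = "poisson", seed = 3)
  counts <- simulate_count_series(spec)
  ws3 <- weekday_summary(counts)
  expect_equal(which.min(ws3$mean), 7L)
})

test_that("grid summaries match a brute-force tally", {
  d <- seq(as.Date("2010-03-02"), by = "7 days", length.out = 4)
  rec <- fire_records(c(d, as.Date("2010-03-07")), 0L, "T",
                      lat = rep(10.1, 5), lon = rep(20.1, 5),
                      confidence = 100L, type = 0L)
  mw <- grid_summary(rec, statistic = "min_weekday")
  expect_equal(nrow(mw), 1L)
  expect_equal(mw$value, 7)  # one Sunday vs four Tuesdays

  cnt <- grid_summary(rec, statistic = "count")
  expect_equal(cnt$value, 5)
  expect_equal(cnt$lon_center, 20.25)
  expect_equal(cnt$lat_center, 10.25)

  set.seed(7)
  n <- 500
  rnd <- fire_records(rep(as.Date("2010-06-01"), n), 0L, "T",
                      lat = runif(n, -20, 20), lon = runif(n, -40, 40),
                      confidence = 100L, type = 0L)
  gs <- grid_summary(rnd, cellsize = 5, statistic = "count")
  brute <- table(paste(floor((90 - rnd$lat) / 5) + 1,
                       floor((rnd$lon + 180) / 5) + 1))
  expect_equal(sum(gs$value), n)
  expect_equal(nrow(gs), length(brute))
  key <- paste(gs$row, gs$col)
  expect_equal(gs$value, as.numeric(brute[key]))
})
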