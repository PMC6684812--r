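test_that("degenerate spec with everything off gives a constant mean", {
  spec <- flat_spec(n_days = 50, a0 = 9.34, sd = 0.5)
  sim <- simulate_log_series(spec)
  expect_equal(sim$true_mean, rep(9.34, 50))
  expect_length(sim$series$values, 50)
})

test_that("preset defaults mirror the fitted global model", {
  spec <- simulation_spec()
  expect_equal(spec$n_days, 3675L)
  expect_equal(as.integer(format(spec$start_date, "%u")), 1L)  # Monday
  expect_equal(spec$a0, 9.3405)
  h <- spec$harmonics
  expect_equal(h$omega[1], 2 * pi / 365)
  expect_equal(h$cos[1], 0.18654)
  expect_equal(h$sin[1], 0.26376)
  expect_equal(h$omega[5:6], c(2 * pi / 7, 4 * pi / 7))
})

test_that("AR(1) noise has the closed-form stationary variance", {
  spec <- flat_spec(n_days = 100000, ar = 0.5, sd = 1, seed = 31)
  sim <- simulate_log_series(spec)
  x <- sim$series$values - sim$true_mean
  expect_lt(abs(var(x) - 1 / (1 - 0.25)) / (1 / (1 - 0.25)), 0.02)
})

test_that("sample mean of the log series recovers the true mean", {
  spec <- flat_spec(n_days = 50000, ar = 0.3, sd = 0.2, seed = 5)
  sim <- simulate_log_series(spec)
  x <- sim$series$values - sim$true_mean
  expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)))
})

test_that("non-stationary AR coefficients are rejected", {
  expect_error(flat_spec(ar = 1.05), "non-stationary")
  expect_error(flat_spec(ar = c(0.6, 0.5)), "non-stationary")
  # boundary unit root
  expect_error(flat_spec(ar = 1), "non-stationary")
})

test_that("count modes behave as documented", {
  spec <- flat_spec(n_days = 30, a0 = log(100), sd = 1e-12)
  expect_error(simulation_spec(innovation_sd = 0), "innovation_sd")
  counts <- simulate_count_series(spec)
  expect_equal(counts$counts, rep(100, 30))

  pois <- flat_spec(n_days = 10000, a0 = log(1000), sd = 1e-12,
                    seed = 8, count_mode = "poisson")
  cp <- simulate_count_series(pois)
  expect_lt(abs(mean(cp$counts) - 1000), 3 * sqrt(1000 / 10000))

  # determinism
  expect_identical(simulate_count_series(pois)$counts,
                   simulate_count_series(pois)$counts)
})

test_that("overflowing count intensities are rejected with the index", {
  spec <- flat_spec(n_days = 3, a0 = 20, a1 = 10, sd = 1e-12)
  expect_error(simulate_count_series(spec), "t = 2")
})

test_that("toy grids follow the block layout and reject overlaps", {
  g <- make_toy_anthrome_grid(2, 3, list(
    list(rows = 1:2, cols = 1:2, code = 31),
    list(rows = 1:2, cols = 3, code = 41)))
  expect_equal(g$codes,
               matrix(c(31, 31, 31, 31, 41, 41), 2, 3))
  expect_error(make_toy_anthrome_grid(2, 2, list(
    list(rows = 1:2, cols = 1:2, code = 31),
    list(rows = 2, cols = 2, code = 41))), "overlap")
  # uncovered cells are nodata and stay unlabeled downstream
  g2 <- make_toy_anthrome_grid(2, 2, list(
    list(rows = 1, cols = 1:2, code = 51)))
  rec <- fire_records(as.Date("2010-01-01"), 0L, "T",
                      lat = 0.25, lon = 0.75, confidence = 80L,
                      type = 0L)
  lab <- assign_anthromes(rec, g2)
  expect_true(is.na(lab$anthrome_code))
  expect_equal(nrow(lab), 1L)
})

test_that("fire-record simulation is deterministic and group-faithful", {
  g <- make_toy_anthrome_grid(2, 2, list(
    list(rows = 1:2, cols = 1, code = 31),
    list(rows = 1:2, cols = 2, code = 41)), cellsize = 1)
  specs <- list(
    Croplands = flat_spec(n_days = 365, a0 = log(100), sd = 1e-12,
                          count_mode = "poisson", seed = 1),
    Rangelands = flat_spec(n_days = 365, a0 = log(10), sd = 1e-12,
                           count_mode = "poisson", seed = 2))
  rec1 <- simulate_fire_records(specs, g, seed = 4)
  rec2 <- simulate_fire_records(specs, g, seed = 4)
  expect_identical(rec1, rec2)
  lab <- assign_anthromes(rec1, g)
  agg <- aggregate_daily(lab, min(lab$acq_date), max(lab$acq_date),
                         group_by = "anthrome_group")
  m <- vapply(agg, function(s) mean(s$counts), numeric(1))
  # Poisson mean recovery within 3 MC standard errors
  expect_lt(abs(m[["Croplands"]] - 100), 3 * sqrt(100 / 365))
  expect_lt(abs(m[["Rangelands"]] - 10), 3 * sqrt(10 / 365))
  expect_error(simulate_fire_records(
    list(Wildlands = specs[[1]]), g, seed = 1), "no grid cell")
})

test_that("a planted Sunday deficit depresses the Sunday record share", {
  g <- make_toy_anthrome_grid(1, 1, list(
    list(rows = 1, cols = 1, code = 31)), cellsize = 1)
  spec <- flat_spec(n_days = 3675, a0 = log(100), sd = 1e-12,
                    weekday_offsets = c(rep(0, 6), -0.10),
                    count_mode = "poisson", seed = 6)
  rec <- simulate_fire_records(list(Croplands = spec), g, seed = 6)
  wd <- as.integer(format(rec$acq_date, "%u"))
  share <- mean(wd == 7L)
  expect_lt(share, 1 / 7)
  # close to the intensity-ratio value exp(-0.1) / (6 + exp(-0.1))
  expect_lt(abs(share - exp(-0.1) / (6 + exp(-0.1))), 0.005)
})

test_that("fire records round-trip through writer, reader and aggregation", {
  g <- make_toy_anthrome_grid(3, 3, list(
    list(rows = 1:3, cols = 1:3, code = 61)), cellsize = 0.5)
  spec <- flat_spec(n_days = 30, a0 = log(25), sd = 0.1, seed = 12)
  rec <- simulate_fire_records(list(Wildlands = spec), g, seed = 12)
  before <- aggregate_daily(rec, spec$start_date,
                            spec$start_date + 29)
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_mcd14ml(rec, path)
  back <- read_mcd14ml(path)
  expect_equal(nrow(back), nrow(rec))
  after <- aggregate_daily(back, spec$start_date, spec$start_date + 29)
  expect_equal(after$counts, before$counts)
  # no spatial loss either: every reread record maps to the same grid
  lab <- assign_anthromes(back, g)
  expect_true(all(lab$anthrome_group == "Wildlands"))
})
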