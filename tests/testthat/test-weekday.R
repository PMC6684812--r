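make_partition <- function(mean, cov, halfwidth, start_weekday = 1L) {
  mfp <- fake_mfp(mean, cov)
  partition_by_weekday(mfp, fake_band(mfp, halfwidth),
                       start_weekday = start_weekday)
}

test_that("weekday partition uses interleaved index arithmetic", {
  mfp <- fake_mfp(rep(0, 364), diag(364))
  band <- fake_band(mfp, 1)
  part <- partition_by_weekday(mfp, band)
  expect_equal(part$indices[[7]], seq(7, 364, by = 7))
  expect_equal(part$indices[[1]], seq(1, 364, by = 7))
  expect_equal(sort(unlist(part$indices)), 1:364)
  expect_equal(part$weeks, 52L)
  expect_equal(dim(part$cross_sunday[[2]]), c(52L, 52L))

  # window starting Wednesday: position 1 is weekday 3
  p3 <- partition_by_weekday(mfp, band, start_weekday = 3L)
  expect_equal(p3$indices[[3]][1], 1L)
  expect_equal(p3$indices[[7]][1], 5L)  # first Sunday is position 5

  short <- fake_mfp(rep(0, 363), diag(363))
  expect_error(partition_by_weekday(short, fake_band(short, 1)),
               "divisible by 7")
  expect_error(partition_by_weekday(mfp, fake_band(short, 1)),
               "do not match")
})

test_that("membership is certain for degenerate identical posteriors", {
  part <- make_partition(rep(1, 28), matrix(0, 28, 28), halfwidth = 0)
  tab <- membership_table(part, n_mc = 2000, seed = 1)
  expect_equal(tab$estimate, rep(1, 7))
  expect_equal(tab$mc_error, rep(0, 7))
})

test_that("exceedance treats exact ties as not above", {
  part <- make_partition(rep(1, 28), matrix(0, 28, 28), halfwidth = 0)
  tab <- exceedance_table(part, n_mc = 2000, seed = 2)
  expect_equal(tab$estimate, rep(0, 7))
})

test_that("one-week equal-mean independent posteriors exceed at rate 1/2", {
  part <- make_partition(rep(0, 7), diag(7), halfwidth = 1)
  tab <- exceedance_table(part, n_mc = 100000, seed = 3)
  for (i in 1:7)  # incl. Sunday: a continuous posterior has no ties
    expect_lt(abs(tab$estimate[i] - 0.5),
              3 * max(tab$mc_error[i], 1e-3))
})

test_that("the strongest-cycle window finds the planted run", {
  weeks <- 30
  mean <- rep(0, weeks * 7)
  sunday_pos <- seq(7, weeks * 7, by = 7)
  mean[sunday_pos] <- -1
  # Tuesday well above Sunday only in weeks 10..20
  tuesday_pos <- seq(2, weeks * 7, by = 7)
  mean[tuesday_pos[10:20]] <- 5
  part <- make_partition(mean, diag(weeks * 7) * 0.01, halfwidth = 1)
  rep10 <- strongest_cycle_window(part)
  expect_gte(rep10$start_week, 10L)
  expect_lte(rep10$end_week, 20L)
  expect_equal(rep10$length, 11L)
  expect_equal(rep10$start_date, part$start_date + 9 * 7)

  # no exceedance anywhere
  none <- make_partition(rep(0, 28), diag(28) * 0.01, halfwidth = 1)
  r0 <- strongest_cycle_window(none)
  expect_equal(r0$length, 0L)
  expect_true(all(r0$profile == 0))
  expect_true(is.na(r0$start_week))

  # every weekday above Sunday's band in every week
  mean2 <- rep(5, 28); mean2[seq(7, 28, 7)] <- -5
  all6 <- make_partition(mean2, diag(28) * 0.01, halfwidth = 1)
  r6 <- strongest_cycle_window(all6)
  expect_equal(r6$length, 4L)
  expect_true(all(r6$profile == 6))
})

test_that("anthrome share table reproduces printed-count arithmetic", {
  counts <- c(Settlements = 139420, Villages = 1545653,
              Croplands = 17043106, Rangelands = 9111319,
              Seminatural = 13555751, Wildlands = 1006472)
  tab <- anthrome_share_table(counts)
  expect_equal(tab$percent,
               c(0.33, 3.65, 40.19, 21.49, 31.97, 2.37))
  expect_lt(abs(sum(tab$percent) - 100), 0.03)

  one <- anthrome_share_table(c(Croplands = 10))
  expect_equal(one$percent[one$group == "Croplands"], 100)

  eq <- anthrome_share_table(
    stats::setNames(rep(7, 6), anthrome_groups()))
  expect_equal(eq$percent, rep(16.67, 6))
})

test_that("the pipeline produces per-group reports and is deterministic", {
  g <- make_toy_anthrome_grid(2, 2, list(
    list(rows = 1:2, cols = 1, code = 31),
    list(rows = 1:2, cols = 2, code = 41)), cellsize = 1)
  specs <- list(
    Croplands = flat_spec(n_days = 140, a0 = log(60), sd = 0.08,
                          count_mode = "poisson", seed = 1),
    Rangelands = flat_spec(n_days = 140, a0 = log(30), sd = 0.08,
                           count_mode = "poisson", seed = 2))
  out <- tempfile(); on.exit(unlink(out, recursive = TRUE))
  cfg <- analysis_config(synthetic = specs, grid = g,
                         freqs = frequency_set(2 * pi / 7),
                         ar_order = 2L, n_mc = 5000L,
                         window_weeks = 8L, seed = 42L, out_dir = out)
  res <- run_pipeline(cfg)
  expect_s3_class(res$global, "series_report")
  expect_setequal(names(res$groups), c("Croplands", "Rangelands"))
  expect_equal(nrow(res$shares), 6L)
  expect_true(all(file.exists(file.path(out, c(
    "table1_shares.csv", "table2_fixed_effects.csv",
    "table3_membership.csv", "table4_exceedance.csv",
    "table5_membership_by_anthrome.csv",
    "table6_exceedance_by_anthrome.csv",
    "band.csv", "cycle_window.csv", "manifest.json")))))

  res2 <- run_pipeline(analysis_config(
    synthetic = specs, grid = g, freqs = frequency_set(2 * pi / 7),
    ar_order = 2L, n_mc = 5000L, window_weeks = 8L, seed = 42L))
  expect_equal(res2$global$membership$estimate,
               res$global$membership$estimate)
  expect_equal(res2$groups$Croplands$band$z, res$groups$Croplands$band$z)
})

test_that("series with zero-count days run with the log offset flagged", {
  spec <- flat_spec(n_days = 140, a0 = log(1.2), sd = 0.3,
                    count_mode = "poisson", seed = 5)
  counts <- simulate_count_series(spec)
  expect_true(any(counts$counts == 0))
  cfg <- analysis_config(freqs = frequency_set(2 * pi / 7),
                         ar_order = 1L, n_mc = 2000L, window_weeks = 4L)
  rep <- analyze_series(counts, cfg, seed = 9)
  expect_equal(rep$log_offset, 1)
})
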