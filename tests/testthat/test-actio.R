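# Actimetry I/O, rebinning, non-wear masking, window selection and brand
# normalization.

write_acttrust_fixture <- function(path, n = 7 * 144, drop_rows = integer(0),
                                   start = as.POSIXct("2019-03-04 00:00:00",
                                                      tz = "UTC")) {
  ts <- start + (seq_len(n) - 1L) * 600
  df <- data.frame(
    `DATE/TIME` = format(ts, "%d/%m/%Y %H:%M:%S"),
    PIM = rep(c(120, 30), length.out = n),
    LIGHT = rep(c(800, 5), length.out = n),
    check.names = FALSE)
  if (length(drop_rows)) df <- df[-drop_rows, ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("a gap-free 7-day 10-min ActTrust file parses to 1008 epochs", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_acttrust_fixture(f)
  s <- read_actimetry_csv(f, "ActTrust")
  expect_s3_class(s, "epoch_series")
  expect_length(s$activity, 1008)
  expect_identical(s$device, "ActTrust")
  expect_identical(s$epoch_min, 10L)
})

test_that("a dropped row becomes a missing epoch, length unchanged", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_acttrust_fixture(f, drop_rows = 500L)
  s <- read_actimetry_csv(f, "ActTrust")
  expect_length(s$activity, 1008)
  expect_identical(sum(is.na(s$activity)), 1L)
  expect_true(is.na(s$activity[500]))
})

test_that("format errors name the first offending row", {
  f <- withr::local_tempfile(fileext = ".csv")
  ts <- as.POSIXct("2019-03-04 00:00:00", tz = "UTC") + (0:99) * 600
  df <- data.frame(`DATE/TIME` = format(ts, "%d/%m/%Y %H:%M:%S"),
                   PIM = 10, LIGHT = 10, check.names = FALSE)
  df$PIM[40] <- -3
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  expect_error(read_actimetry_csv(f, "ActTrust"), "row 40")
  df$PIM[40] <- 10
  df$`DATE/TIME`[60] <- df$`DATE/TIME`[10]   # non-monotone
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  expect_error(read_actimetry_csv(f, "ActTrust"), "row 60")
})

test_that("Actiwatch2 dialect parses and wrong columns are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  ts <- as.POSIXct("2019-03-04 00:00:00", tz = "UTC") + (0:143) * 600
  write.csv(data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
                       activity = 50, white_light = 100),
            f, row.names = FALSE, quote = FALSE)
  s <- read_actimetry_csv(f, "Actiwatch2")
  expect_identical(s$device, "Actiwatch2")
  expect_length(s$activity, 144)
  expect_error(read_actimetry_csv(f, "ActTrust"), "columns")
})

test_that("canonical CSV round-trips a synthetic series identically", {
  s <- make_clean_series(seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_epoch_series_csv(s, f)
  r <- read_epoch_series_csv(f)
  expect_equal(r$activity, s$activity)
  expect_equal(r$light, s$light)
  expect_identical(r$wear, s$wear)
  expect_identical(r$device, s$device)
  expect_identical(r$epoch_min, s$epoch_min)
  expect_equal(r$start_time, s$start_time)
})

test_that("rebin sums activity, averages light, majority-rules missingness", {
  act <- rep(3, 10); lux <- rep(100, 10)
  s <- epoch_series("r", "2019-03-04 00:00:00", 1, act, lux)
  out <- rebin(s, 10)
  expect_equal(out$activity, 30)
  expect_equal(out$light, 100)
  # 6 of 10 source epochs missing -> target missing; 5 of 10 -> kept
  act2 <- c(rep(NA, 6), rep(3, 4), rep(NA, 5), rep(3, 5))
  s2 <- epoch_series("r", "2019-03-04 00:00:00", 1, act2, rep(1, 20))
  out2 <- rebin(s2, 10)
  expect_true(is.na(out2$activity[1]))
  expect_equal(out2$activity[2], 15)
  expect_error(rebin(s, 15.5), "multiple")
})

test_that("non-wear rule masks runs of >= min_run zeros only", {
  base <- rep(50, 300)
  base[101:109] <- 0                  # 9 zeros: below threshold
  base[201:210] <- 0                  # exactly 10: masked
  s <- epoch_series("n", "2019-03-04 00:00:00", 10, base, rep(10, 300))
  out <- detect_nonwear(s, min_run = 10)
  expect_false(anyNA(out$activity[101:109]))
  expect_true(all(is.na(out$activity[201:210])))
  expect_true(all(is.na(out$light[201:210])))   # both channels masked
  expect_true(all(!out$wear[201:210]))
  runs <- attr(out, "nonwear_runs")
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$length, 10L)
  # masking only removes information
  expect_gte(sum(!out$wear), sum(!s$wear))
})

test_that("an all-zero series is fully masked", {
  s <- epoch_series("z", "2019-03-04 00:00:00", 10, rep(0, 144), rep(0, 144))
  out <- detect_nonwear(s)
  expect_true(all(!out$wear))
})

test_that("window selection takes the earliest clean 7 days", {
  s <- make_clean_series(seed = 4, n_days = 10)
  qc <- select_analysis_window(s)
  expect_s3_class(qc, "qc_result")
  expect_length(qc$series$activity, 7 * 144)
  expect_equal(qc$series$start_time, s$start_time)  # first window qualifies
  expect_identical(qc$report$days_retained, 7L)
})

test_that("a day with exactly 4 h missing is accepted, 4 h 10 min is not", {
  mk <- function(extra_missing) {
    act <- rep(60, 7 * 144)
    miss <- 24 + extra_missing          # epochs of day 3 set missing
    act[(2 * 144 + 1):(2 * 144 + miss)] <- NA
    epoch_series("w", "2019-03-04 00:00:00", 10, act,
                 rep(1, 7 * 144))
  }
  ok <- select_analysis_window(mk(0))       # 24 epochs = exactly 4 h
  expect_false(is.null(ok$series))
  bad <- select_analysis_window(mk(1))      # 25 epochs = 4 h 10 min
  expect_null(bad$series)
  expect_identical(bad$report$reason, "NO_CLEAN_WINDOW")
  # oracle: exhaustive scan over candidate day-aligned windows agrees
  day_missing <- bad$report$day_missing_min
  any_window <- any(vapply(1:1, function(d) {
    all(day_missing[d:(d + 6)] <= 240)
  }, logical(1)))
  expect_false(any_window)
})

test_that("short series and series with no clean stretch are rejected", {
  s <- make_clean_series(seed = 5, n_days = 3)
  qc <- select_analysis_window(s)
  expect_null(qc$series)
  expect_identical(qc$report$reason, "TOO_SHORT")
})

test_that("windows are calendar-aligned when the recording starts mid-day", {
  sp <- series_params(n_days = 9, nonwear_bouts = 0)
  s <- simulate_epoch_series(sp, seed = 6,
                             start_time = as.POSIXct("2019-03-04 15:30:00",
                                                     tz = "UTC"))
  qc <- select_analysis_window(s)
  expect_false(is.null(qc$series))
  lt <- as.POSIXlt(qc$series$start_time)
  expect_identical(lt$hour + lt$min, 0L)    # starts at local midnight
  expect_length(qc$series$activity, 7 * 144)
})

test_that("brand normalization matches pooled moments and passes reference through", {
  ref_series <- lapply(1:3, function(i) make_clean_series(seed = 10 + i))
  ref <- brand_reference(ref_series, "Actiwatch2")
  # synthetic ActTrust series = 2 x a reference-like series
  s <- make_clean_series(seed = 14)
  s2 <- epoch_series(s$subject_id, s$start_time, s$epoch_min,
                     2 * s$activity, 2 * s$light, device = "ActTrust")
  out <- normalize_brand(s2, ref)
  m <- mean(out$activity[out$wear], na.rm = TRUE)
  sdv <- sd(out$activity[out$wear], na.rm = TRUE)
  # direct moment oracle (up to zero-clipping of a few rescaled epochs)
  expect_equal(m, unname(ref$activity["mean"]), tolerance = 0.02)
  expect_equal(sdv, unname(ref$activity["sd"]), tolerance = 0.02)
  # reference-device input passes through unchanged
  pass <- normalize_brand(ref_series[[1]], ref)
  expect_equal(pass$activity, ref_series[[1]]$activity)
  # IV is invariant under a positive affine rescaling of the channel
  aff <- epoch_series(s$subject_id, s$start_time, s$epoch_min,
                      3.7 * s$activity + 11, 3.7 * s$light + 11,
                      device = s$device)
  expect_equal(intradaily_variability(aff), intradaily_variability(s),
               tolerance = 1e-12)
  # zero-variance channel errors
  flat <- epoch_series("f", "2019-03-04 00:00:00", 10,
                       rep(5, 1008), rep(5, 1008), device = "ActTrust")
  expect_error(normalize_brand(flat, ref), "zero-variance")
})
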