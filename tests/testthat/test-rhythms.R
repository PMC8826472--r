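# Cosinor, daily profiles, and the non-parametric circadian metrics.

test_that("cosinor recovers a noise-free cosinusoid to machine precision", {
  h <- (0:1007) * 10 / 60
  x <- 5 + 3 * cos(2 * pi * (h - 14) / 24)
  s <- epoch_series("c", "2019-03-04 00:00:00", 10, x, x)
  fit <- fit_cosinor(s)
  expect_equal(fit$mesor, 5, tolerance = 1e-9)
  expect_equal(fit$amplitude, 3, tolerance = 1e-9)
  expect_equal(fit$acrophase_h, 14, tolerance = 1e-9)
  expect_equal(fit$goodness, 1, tolerance = 1e-9)
})

test_that("cosinor on a constant series gives amplitude 0 and goodness 0", {
  s <- epoch_series("c", "2019-03-04 00:00:00", 10, rep(7, 1008), rep(7, 1008))
  fit <- fit_cosinor(s)
  expect_equal(fit$mesor, 7, tolerance = 1e-9)
  expect_equal(fit$amplitude, 0, tolerance = 1e-9)
  expect_equal(fit$goodness, 0)
})

test_that("cosinor is unbiased on noisy simulated cosinusoids", {
  # additive noise around a known cosinusoid; mean estimate within 2 SE
  h <- (0:1007) * 10 / 60
  truth_amp <- 40
  ests <- vapply(1:200, function(seed) {
    set.seed(seed)
    x <- pmax(0, 100 + truth_amp * cos(2 * pi * (h - 15) / 24) + rnorm(1008, 0, 20))
    s <- epoch_series("c", "2019-03-04 00:00:00", 10, x, x)
    fit_cosinor(s)$amplitude
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth_amp), 2 * se + 0.5)
})

test_that("cosinor recovers generator parameters on a noisy schedule-free signal", {
  sp <- series_params(mode = "cosine", noise_cv = 0, nonwear_bouts = 0)
  s <- simulate_epoch_series(sp, seed = 8)
  fit <- fit_cosinor(s)
  expect_equal(fit$mesor, (250 + 15) / 2, tolerance = 0.05)
  expect_equal(fit$amplitude, (250 - 15) / 2, tolerance = 0.05)
  expect_equal(fit$acrophase_h, 15, tolerance = 0.05)
})

test_that("daily profile reduces days bin-wise with the requested stat", {
  # three days whose bin values are 2, 4, 6 -> mean 4, median 4
  day <- rep(1, 144)
  act <- c(day * 2, day * 4, day * 6)
  s <- epoch_series("p", "2019-03-04 00:00:00", 10, act, act)
  pm <- daily_profile(s, "activity", "mean")
  expect_equal(unique(pm$values), 4)
  expect_equal(unique(pm$n_days), 3L)
  # median robustness: days 1, 1, 100
  act2 <- c(day, day, day * 100)
  s2 <- epoch_series("p", "2019-03-04 00:00:00", 10, act2, act2)
  expect_equal(unique(daily_profile(s2, "activity", "median")$values), 1)
  # identical days: profile equals any single day
  patt <- runif(144, 0, 100)
  s3 <- tile_series(patt, n_days = 4)
  expect_equal(daily_profile(s3, "activity", "mean")$values, patt)
})

test_that("group profile equals a naive per-bin recompute", {
  profs <- lapply(1:3, function(i) {
    daily_profile(make_clean_series(seed = 20 + i), "activity", "mean")
  })
  gp_med <- group_profile(profs, "median")
  mat <- do.call(rbind, lapply(profs, `[[`, "values"))
  expect_equal(gp_med$values, apply(mat, 2, median))
  gp_mean <- group_profile(profs, "mean")
  expect_equal(gp_mean$values, colMeans(mat))
  expect_equal(gp_mean$se, apply(mat, 2, sd) / sqrt(3))
  # single subject: group profile is that profile
  expect_equal(group_profile(profs[1], "median")$values, profs[[1]]$values)
  # constant profiles 10 and 30 -> 20
  cp <- lapply(c(10, 30), function(v) {
    daily_profile(tile_series(rep(v, 144), 2), "activity", "mean")
  })
  expect_equal(unique(group_profile(cp, "mean")$values), 20)
  # mixed epoch sizes refuse
  p60 <- daily_profile(rebin(make_clean_series(seed = 30), 60), "activity")
  expect_error(group_profile(list(profs[[1]], p60)), "share")
})

test_that("IS is exactly 1 for a signal repeating identically every 24 h", {
  set.seed(77)
  patt <- runif(144, 0, 200)
  s <- tile_series(patt, n_days = 7)
  expect_equal(interdaily_stability(s), 1, tolerance = 1e-12)
})

test_that("IS of iid noise over 7 days is about 1/7", {
  vals <- vapply(1:200, function(seed) {
    set.seed(seed)
    x <- abs(rnorm(1008, 100, 30))
    interdaily_stability(
      epoch_series("n", "2019-03-04 00:00:00", 10, x, x))
  }, numeric(1))
  expect_equal(mean(vals), 1 / 7, tolerance = 0.05 / (1 / 7))
})

test_that("IS/IV guard degenerate inputs", {
  flat <- epoch_series("f", "2019-03-04 00:00:00", 10, rep(5, 1008),
                       rep(5, 1008))
  expect_error(interdaily_stability(flat), "zero-variance")
  expect_error(intradaily_variability(flat), "zero-variance")
  short <- epoch_series("s", "2019-03-04 00:00:00", 10, runif(144), runif(144))
  expect_error(interdaily_stability(short), "2 days")
  sparse <- epoch_series("sp", "2019-03-04 00:00:00", 10,
                         c(runif(300), rep(NA, 708)), rep(1, 1008))
  expect_error(intradaily_variability(sparse), "present")
})

test_that("IV matches the sampled-sinusoid closed form and the white-noise level", {
  h <- (0:1007) * 10 / 60
  x <- 10 + 5 * cos(2 * pi * h / 24)
  s <- epoch_series("v", "2019-03-04 00:00:00", 10, x, x)
  iv <- intradaily_variability(s)
  expect_equal(iv, 2 * (1 - cos(2 * pi / 144)), tolerance = 0.01)
  expect_equal(round(iv, 1), 0)
  set.seed(123)
  g <- abs(rnorm(1008, 200, 20))
  sg <- epoch_series("g", "2019-03-04 00:00:00", 10, g, g)
  expect_equal(intradaily_variability(sg), 2, tolerance = 0.15)
})

test_that("IS and IV are invariant under positive affine transforms", {
  for (seed in 1:5) {
    s <- make_clean_series(seed = 400 + seed)
    a <- runif(1, 0.5, 5); b <- runif(1, 0, 50)
    s2 <- epoch_series(s$subject_id, s$start_time, s$epoch_min,
                       a * s$activity + b, a * s$light + b, wear = s$wear)
    expect_equal(interdaily_stability(s2), interdaily_stability(s),
                 tolerance = 1e-12)
    expect_equal(intradaily_variability(s2), intradaily_variability(s),
                 tolerance = 1e-12)
  }
})

test_that("IV with missing epochs uses only consecutive non-missing pairs", {
  set.seed(9)
  x <- abs(rnorm(1008, 100, 25))
  x[c(200:220, 700:710)] <- NA
  s <- epoch_series("m", "2019-03-04 00:00:00", 10, x, rep(1, 1008))
  keep <- !is.na(x)
  pair <- keep[-1] & keep[-length(x)]
  d <- diff(x)[pair]
  N <- sum(pair) + 1
  manual <- N * sum(d^2) / ((N - 1) * sum((x[keep] - mean(x[keep]))^2))
  expect_equal(intradaily_variability(s), manual, tolerance = 1e-12)
})

test_that("M10/L5 equal the brute-force window scan on random profiles", {
  set.seed(55)
  for (i in 1:25) {
    s <- make_clean_series(seed = 500 + i)
    prof <- daily_profile(s, "activity", "mean")
    got <- m10_l5(prof)
    o10 <- oracle_window_extreme(prof$values, 60, "max")
    o5 <- oracle_window_extreme(prof$values, 30, "min")
    expect_identical(got$M10, o10$value)
    expect_identical(got$M10_onset_h, prof$clock_h[o10$onset])
    expect_identical(got$L5, o5$value)
    expect_identical(got$L5_onset_h, prof$clock_h[o5$onset])
  }
})

test_that("M10/L5 handle square waves, wrap-around and constants", {
  # square wave high 08:00-20:00
  hrs <- (0:143) * 10 / 60
  sq <- ifelse(hrs >= 8 & hrs < 20, 100, 0)
  got <- m10_l5(daily_profile(tile_series(sq, 2), "activity", "mean"))
  expect_equal(got$M10, 100)
  expect_true(got$M10_onset_h >= 8 && got$M10_onset_h < 20)
  expect_equal(got$L5, 0)
  # lowest block spanning midnight: 22:00-03:00
  low <- ifelse(hrs >= 22 | hrs < 3, 0, 50)
  got2 <- m10_l5(daily_profile(tile_series(low, 2), "activity", "mean"))
  expect_equal(got2$L5, 0)
  expect_equal(got2$L5_onset_h, 22)
  # constant profile: M10 = L5 = c
  gc <- m10_l5(daily_profile(tile_series(rep(4, 144), 2), "activity", "mean"))
  expect_equal(gc$M10, 4)
  expect_equal(gc$L5, 4)
  # median profiles are refused
  expect_error(m10_l5(daily_profile(tile_series(sq, 2), "activity", "median")),
               "mean")
})

test_that("relative amplitude and its log-light variant follow the formulas", {
  expect_equal(relative_amplitude(100, 0), 1)
  expect_equal(relative_amplitude(50, 50), 0)
  expect_equal(relative_amplitude(300, 100), 0.5)
  expect_error(relative_amplitude(0, 0), "undefined")
  expect_equal(log_light_ra(990, 0), 0.5)
  expect_equal(log_light_ra(37, 37), 0)
  expect_equal(log_light_ra(90, 0), 1 / 3, tolerance = 1e-12)
  expect_error(log_light_ra(-1, 0), "non-negative")
})

test_that("rhythm_metrics assembles a consistent per-channel row", {
  s <- make_clean_series(seed = 60)
  row <- rhythm_metrics(s, "activity")
  expect_true(row$IS >= 0 && row$IS <= 1 + 1e-9)
  expect_gte(row$IV, 0)
  expect_gte(row$M10, row$L5)
  expect_equal(row$RA, (row$M10 - row$L5) / (row$M10 + row$L5))
  expect_true(is.na(row$RA_log))
  lrow <- rhythm_metrics(s, "light")
  expect_equal(lrow$RA_log, log_light_ra(lrow$M10, lrow$L5))
})
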