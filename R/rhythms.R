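# Non-parametric circadian rhythm analysis (NPCRA) and single cosinor.
#
# All metrics operate on one channel of an epoch series; missing epochs
# (device gaps, non-wear) are excluded as documented per metric.

channel_values <- function(series, channel = c("activity", "light")) {
  channel <- match.arg(channel)
  series[[channel]]
}

#' Single-cosinor fit
#'
#' Least-squares fit of `x(t) = M + A * cos(2*pi*(t - phi)/period)` through the
#' linear cos/sin parameterization, over non-missing epochs only. The
#' acrophase is reported as the clock time (decimal hours) at which the fitted
#' curve peaks.
#'
#' @param series an [epoch_series].
#' @param channel `"activity"` or `"light"`.
#' @param period_h fitted period in hours (default 24).
#' @return list of class `cosinor_fit`: `channel`, `mesor`, `amplitude`,
#'   `acrophase_h` in `[0, 24)`, and `goodness` (fraction of variance
#'   explained, 0 for a flat fit).
#' @export
fit_cosinor <- function(series, channel = c("activity", "light"),
                        period_h = 24) {
  channel <- match.arg(channel)
  x <- channel_values(series, channel)
  keep <- !is.na(x)
  if (sum(keep) < 3L) stop("too few data points for a cosinor fit", call. = FALSE)
  # time as clock hours continued past 24 so phi is directly a clock time
  t_abs <- epoch_clock_hours(series)[1] + epoch_elapsed_hours(series)
  theta <- 2 * pi * t_abs[keep] / period_h
  fit <- lm(x[keep] ~ cos(theta) + sin(theta))
  b <- coef(fit)
  amp <- sqrt(b[2]^2 + b[3]^2)
  phi <- (atan2(b[3], b[2]) * period_h / (2 * pi)) %% period_h
  ssr <- sum(fit$residuals^2)
  sst <- sum((x[keep] - mean(x[keep]))^2)
  structure(list(channel = channel, mesor = unname(b[1]),
                 amplitude = unname(amp), acrophase_h = unname(phi %% 24),
                 goodness = if (sst > 0) max(0, 1 - ssr / sst) else 0),
            class = "cosinor_fit")
}

#' Per-subject daily (24 h) profile
#'
#' Folds the series onto the 24 h clock and summarises each within-day bin
#' over the days that have data in that bin.
#'
#' @param series an [epoch_series].
#' @param channel `"activity"` or `"light"`.
#' @param stat `"mean"` or `"median"`.
#' @return list of class `daily_profile`: `channel`, `epoch_min`, `stat`,
#'   `values` (one per within-day bin, NA where no day contributes),
#'   `n_days` contributing per bin, and `clock_h` of each bin start.
#' @export
daily_profile <- function(series, channel = c("activity", "light"),
                          stat = c("mean", "median")) {
  channel <- match.arg(channel)
  stat <- match.arg(stat)
  x <- channel_values(series, channel)
  p <- 1440L %/% series$epoch_min
  bin <- (round(epoch_clock_hours(series) * 60 / series$epoch_min) %% p) + 1L
  f <- if (stat == "mean") mean else median
  values <- rep(NA_real_, p)
  n_days <- integer(p)
  for (b in seq_len(p)) {
    v <- x[bin == b]
    v <- v[!is.na(v)]
    n_days[b] <- length(v)
    if (length(v)) values[b] <- f(v)
  }
  structure(list(channel = channel, epoch_min = series$epoch_min, stat = stat,
                 values = values, n_days = n_days,
                 clock_h = (seq_len(p) - 1L) * series$epoch_min / 60),
            class = "daily_profile")
}

#' Group-level daily profile across subjects
#'
#' Bin-wise mean or median across subjects' individual daily profiles; for
#' mean profiles the bin-wise standard error across subjects is also returned
#' (the shading of group profile figures).
#'
#' @param profiles list of [daily_profile] objects sharing channel and epoch.
#' @param stat `"mean"` or `"median"`.
#' @return a `daily_profile` with an extra `se` element (NA for medians).
#' @export
group_profile <- function(profiles, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!length(profiles)) stop("no profiles supplied", call. = FALSE)
  em <- vapply(profiles, function(p) p$epoch_min, numeric(1))
  ch <- vapply(profiles, function(p) p$channel, character(1))
  if (length(unique(em)) != 1L || length(unique(ch)) != 1L) {
    stop("profiles must share epoch length and channel", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(profiles, function(p) p$values))
  f <- if (stat == "mean") mean else median
  values <- apply(mat, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) f(v) else NA_real_
  })
  se <- if (stat == "mean") {
    apply(mat, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    })
  } else rep(NA_real_, ncol(mat))
  n_subj <- apply(mat, 2, function(v) sum(!is.na(v)))
  structure(list(channel = ch[1], epoch_min = em[1], stat = stat,
                 values = values, se = se, n_days = n_subj,
                 clock_h = profiles[[1]]$clock_h),
            class = "daily_profile")
}

# Shared guard: refuse IS/IV when too little of the series is observed.
check_coverage <- function(x, min_coverage) {
  cov <- mean(!is.na(x))
  if (cov < min_coverage) {
    stop(sprintf("only %.0f%% of epochs present (< %.0f%% required)",
                 100 * cov, 100 * min_coverage), call. = FALSE)
  }
}

#' Interdaily stability (IS)
#'
#' Fraction of the series' variance explained by its average 24 h pattern:
#' `IS = (N * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)` with `p`
#' within-day bins, `N` non-missing epochs, `xbar_h` the across-day mean of
#' bin `h`. Ranges 0 (no day-to-day regularity) to 1 (a pattern repeating
#' identically every 24 h); values slightly above 1 can only arise from
#' missing-data imbalance and are flagged with a warning.
#'
#' @param series an [epoch_series].
#' @param channel `"activity"` or `"light"`.
#' @param min_coverage minimum fraction of non-missing epochs (default 0.8).
#' @return IS, a dimensionless scalar.
#' @export
interdaily_stability <- function(series, channel = c("activity", "light"),
                                 min_coverage = 0.8) {
  channel <- match.arg(channel)
  x <- channel_values(series, channel)
  if (length(x) * series$epoch_min < 2 * 1440) {
    stop("at least 2 days are required for IS", call. = FALSE)
  }
  check_coverage(x, min_coverage)
  p <- 1440L %/% series$epoch_min
  bin <- (round(epoch_clock_hours(series) * 60 / series$epoch_min) %% p) + 1L
  keep <- !is.na(x)
  N <- sum(keep)
  xbar <- mean(x[keep])
  denom <- sum((x[keep] - xbar)^2)
  if (denom == 0) stop("zero-variance series; IS undefined", call. = FALSE)
  hmeans <- tapply(x[keep], bin[keep], mean)
  is_val <- N * sum((hmeans - xbar)^2) / (p * denom)
  if (is_val > 1 + 1e-9) {
    warning(sprintf("IS = %.4f > 1 (missing-data imbalance)", is_val))
  }
  unname(is_val)
}

#' Intradaily variability (IV)
#'
#' Rhythm fragmentation as the normalized mean-square successive difference:
#' `IV = (N * sum (x_i - x_(i-1))^2) / ((N - 1) * sum (x_i - xbar)^2)`.
#' Successive differences are taken only across consecutive non-missing epoch
#' pairs; `N` is the number of such pairs plus one, so a gap-free series gives
#' the classical estimator. IV is near 0 for a smooth sinusoid and about 2
#' for Gaussian white noise; higher means more fragmented.
#'
#' @inheritParams interdaily_stability
#' @return IV, a dimensionless scalar.
#' @export
intradaily_variability <- function(series, channel = c("activity", "light"),
                                   min_coverage = 0.8) {
  channel <- match.arg(channel)
  x <- channel_values(series, channel)
  check_coverage(x, min_coverage)
  keep <- !is.na(x)
  pair <- keep[-1] & keep[-length(keep)]
  if (!any(pair)) stop("no consecutive non-missing pairs; IV undefined",
                       call. = FALSE)
  d <- diff(x)[pair]
  N <- sum(pair) + 1L
  xbar <- mean(x[keep])
  denom <- sum((x[keep] - xbar)^2)
  if (denom == 0) stop("zero-variance series; IV undefined", call. = FALSE)
  # denominator variance uses all non-missing epochs
  unname(N * sum(d^2) / ((N - 1) * denom))
}

#' M10 and L5 of a mean daily profile
#'
#' Exhaustive scan of every circular window of 10 consecutive hours (M10,
#' highest mean) and 5 consecutive hours (L5, lowest mean) over the 24 h mean
#' profile, wrapping across midnight. Ties resolve to the earliest onset
#' clock time. Undefined bins are imputed with the profile mean (and a
#' message emitted) so the window means stay comparable.
#'
#' @param profile a [daily_profile] computed with `stat = "mean"`.
#' @return list: `M10`, `M10_onset_h`, `L5`, `L5_onset_h`.
#' @export
m10_l5 <- function(profile) {
  if (profile$stat != "mean") {
    stop("M10/L5 are defined on the mean daily profile", call. = FALSE)
  }
  v <- profile$values
  if (all(is.na(v))) stop("profile has no defined bins", call. = FALSE)
  if (anyNA(v)) {
    message(sum(is.na(v)), " undefined profile bins imputed with profile mean")
    v[is.na(v)] <- mean(v, na.rm = TRUE)
  }
  p <- length(v)
  win_mean <- function(len_bins) {
    vv <- c(v, v[seq_len(len_bins - 1L)])
    vapply(seq_len(p), function(i) mean(vv[i:(i + len_bins - 1L)]), numeric(1))
  }
  nb10 <- as.integer(10 * 60 / profile$epoch_min)
  nb5 <- as.integer(5 * 60 / profile$epoch_min)
  w10 <- win_mean(nb10)
  w5 <- win_mean(nb5)
  i10 <- which.max(w10)   # which.max returns the first (earliest) maximum
  i5 <- which.min(w5)
  list(M10 = w10[i10], M10_onset_h = profile$clock_h[i10],
       L5 = w5[i5], L5_onset_h = profile$clock_h[i5])
}

#' Relative amplitude
#'
#' `RA = (M10 - L5) / (M10 + L5)`, the normalized day-night contrast.
#'
#' @param M10,L5 window means from [m10_l5()].
#' @return RA in `[0, 1]` for non-negative channels.
#' @export
relative_amplitude <- function(M10, L5) {
  if (M10 + L5 == 0) stop("M10 + L5 = 0; RA undefined", call. = FALSE)
  (M10 - L5) / (M10 + L5)
}

#' Log-scale relative amplitude for light exposure
#'
#' Light L5 is very often near 0 lux, which compresses plain RA against 1; the
#' log-offset variant
#' `(log10(M10 + 10) - log10(L5 + 10)) / (log10(M10 + 10) + log10(L5 + 10))`
#' spreads the scale and stays defined at L5 = 0.
#'
#' @param M10,L5 light window means (lux), non-negative.
#' @return dimensionless log-scale RA.
#' @export
log_light_ra <- function(M10, L5) {
  if (M10 < 0 || L5 < 0) stop("M10 and L5 must be non-negative", call. = FALSE)
  a <- log10(M10 + 10); b <- log10(L5 + 10)
  (a - b) / (a + b)
}

#' All rhythm metrics for one channel of a series
#'
#' Convenience wrapper producing the per-subject, per-channel row used by the
#' pipeline: IS, IV, M10/L5 with onsets, RA (plus log-RA for light), and the
#' cosinor mesor/amplitude/acrophase.
#'
#' @param series an [epoch_series] (preprocessed).
#' @param channel `"activity"` or `"light"`.
#' @return one-row data frame.
#' @export
rhythm_metrics <- function(series, channel = c("activity", "light")) {
  channel <- match.arg(channel)
  prof <- daily_profile(series, channel, stat = "mean")
  ml <- m10_l5(prof)
  cf <- fit_cosinor(series, channel)
  data.frame(
    subject_id = series$subject_id, channel = channel,
    IS = interdaily_stability(series, channel),
    IV = intradaily_variability(series, channel),
    M10 = ml$M10, M10_onset = ml$M10_onset_h,
    L5 = ml$L5, L5_onset = ml$L5_onset_h,
    RA = relative_amplitude(ml$M10, ml$L5),
    RA_log = if (channel == "light") log_light_ra(ml$M10, ml$L5) else NA_real_,
    mesor = cf$mesor, amplitude = cf$amplitude, acrophase_h = cf$acrophase_h,
    stringsAsFactors = FALSE)
}
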