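# Preprocessing of raw actimetry: rebinning, non-wear detection, selection of
# the 7-day analysis window, and between-device normalization.

#' Rebin an epoch series to a coarser epoch length
#'
#' Activity counts are summed within each target bin and light is averaged,
#' matching how the two channels accumulate physically. A target bin is set
#' missing when more than half of its source epochs are missing.
#'
#' @param series an [epoch_series].
#' @param target_epoch_min new epoch length; must be a multiple of the current
#'   one and divide 1440.
#' @return a rebinned [epoch_series].
#' @export
rebin <- function(series, target_epoch_min) {
  k <- target_epoch_min / series$epoch_min
  if (k %% 1 != 0 || k < 1) {
    stop("target_epoch_min must be a multiple of the source epoch length",
         call. = FALSE)
  }
  k <- as.integer(k)
  if (k == 1L) return(series)
  n_out <- length(series$activity) %/% k
  idx <- rep(seq_len(n_out), each = k)
  used <- seq_len(n_out * k)
  agg <- function(x, f) {
    miss <- tapply(is.na(x[used]), idx, sum)
    val <- tapply(x[used], idx, function(v) {
      if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE)
    })
    val[miss > k / 2] <- NA_real_
    as.numeric(val)
  }
  activity <- agg(series$activity, sum)
  light <- agg(series$light, mean)
  wear <- as.logical(tapply(series$wear[used], idx, function(w) mean(w) > 0.5))
  epoch_series(series$subject_id, series$start_time, target_epoch_min,
               activity, light, wear = wear, device = series$device)
}

#' Detect non-wear periods as long runs of zero activity
#'
#' Every maximal run of at least `min_run` consecutive zero-activity epochs is
#' treated as off-wrist: the wear mask is cleared and both channels are set
#' missing across the run (lux from a pocketed device is as invalid as its
#' counts). Shorter zero runs are left untouched.
#'
#' @param series an [epoch_series].
#' @param min_run minimum run length in epochs (default 10, i.e. 100 min at
#'   10-min epochs).
#' @return the series with non-wear masked; the attribute `nonwear_runs` holds
#'   a data frame of the runs found (start epoch, length).
#' @export
detect_nonwear <- function(series, min_run = 10) {
  stopifnot_scalar(min_run, "min_run", 1)
  is_zero <- !is.na(series$activity) & series$activity == 0
  r <- rle(is_zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  runs <- data.frame(start = starts[hit], length = r$lengths[hit])
  for (i in seq_len(nrow(runs))) {
    span <- runs$start[i]:(runs$start[i] + runs$length[i] - 1L)
    series$wear[span] <- FALSE
    series$activity[span] <- NA_real_
    series$light[span] <- NA_real_
  }
  attr(series, "nonwear_runs") <- runs
  series
}

#' Select the analysis window of consecutive complete days
#'
#' Scans calendar-aligned (midnight-to-midnight) days and returns the earliest
#' run of `n_days` consecutive days in which every day has at most
#' `max_missing_h_per_day` hours of missing data. Missing means NA activity,
#' whether from device gaps or from non-wear masking, so [detect_nonwear()]
#' should be applied first.
#'
#' @param series an [epoch_series].
#' @param n_days window length in days (default 7).
#' @param max_missing_h_per_day inclusive per-day missing-data budget in hours
#'   (default 4).
#' @return a list of class `qc_result` with elements `series` (the selected
#'   [epoch_series], or NULL if rejected) and `report` (subject id, per-day
#'   missing minutes, selected window start, days retained, rejection reason).
#' @export
select_analysis_window <- function(series, n_days = 7,
                                   max_missing_h_per_day = 4) {
  ep_per_day <- 1440L %/% series$epoch_min
  lt <- as.POSIXlt(series$start_time)
  mins_into_day <- lt$hour * 60 + lt$min
  # first epoch index that starts a calendar day
  off <- if (mins_into_day == 0) 0L else {
    as.integer((1440 - mins_into_day) / series$epoch_min)
  }
  n <- length(series$activity)
  n_full_days <- (n - off) %/% ep_per_day
  report <- list(subject_id = series$subject_id, day_missing_min = numeric(0),
                 window_start = NA, days_retained = 0L, reason = NA_character_)
  if (n_full_days < n_days) {
    report$reason <- "TOO_SHORT"
    return(structure(list(series = NULL, report = report), class = "qc_result"))
  }
  day_missing <- vapply(seq_len(n_full_days), function(d) {
    span <- (off + (d - 1L) * ep_per_day + 1L):(off + d * ep_per_day)
    sum(is.na(series$activity[span])) * series$epoch_min
  }, numeric(1))
  report$day_missing_min <- day_missing
  ok <- day_missing <= max_missing_h_per_day * 60
  start_day <- NA_integer_
  for (d in seq_len(n_full_days - n_days + 1L)) {
    if (all(ok[d:(d + n_days - 1L)])) { start_day <- d; break }
  }
  if (is.na(start_day)) {
    report$reason <- "NO_CLEAN_WINDOW"
    return(structure(list(series = NULL, report = report), class = "qc_result"))
  }
  span <- (off + (start_day - 1L) * ep_per_day + 1L):
    (off + (start_day + n_days - 1L) * ep_per_day)
  out <- epoch_series(series$subject_id,
                      series$start_time + (span[1] - 1L) * series$epoch_min * 60,
                      series$epoch_min,
                      series$activity[span], series$light[span],
                      wear = series$wear[span], device = series$device)
  report$window_start <- out$start_time
  report$days_retained <- as.integer(n_days)
  structure(list(series = out, report = report), class = "qc_result")
}

#' Pooled reference moments for brand normalization
#'
#' Computes the pooled mean and SD of each channel over wear epochs of the
#' reference-device recordings.
#'
#' @param series_list list of [epoch_series].
#' @param reference_device device tag of the reference pool.
#' @return list with `device`, and per-channel `mean`/`sd`.
#' @export
brand_reference <- function(series_list, reference_device = "Actiwatch2") {
  refs <- Filter(function(s) s$device == reference_device, series_list)
  if (!length(refs)) {
    stop("no series from the reference device", call. = FALSE)
  }
  act <- unlist(lapply(refs, function(s) s$activity[s$wear]))
  lux <- unlist(lapply(refs, function(s) s$light[s$wear]))
  out <- list(device = reference_device,
              activity = c(mean = mean(act, na.rm = TRUE),
                           sd = sd(act, na.rm = TRUE)),
              light = c(mean = mean(lux, na.rm = TRUE),
                        sd = sd(lux, na.rm = TRUE)))
  if (out$activity["sd"] == 0 || out$light["sd"] == 0) {
    stop("zero-variance reference channel", call. = FALSE)
  }
  out
}

#' Normalize a recording to the reference device's scale
#'
#' Non-reference recordings are linearly rescaled per channel, over wear
#' epochs, so that the pooled mean and SD of the rescaled series pool match
#' the reference pool; reference-device recordings pass through unchanged.
#' Rescaled values falling below zero are clipped to 0 and counted.
#'
#' @param series an [epoch_series].
#' @param reference output of [brand_reference()].
#' @return the normalized series; attribute `clipped` counts clipped epochs.
#' @export
normalize_brand <- function(series, reference) {
  if (series$device == reference$device) {
    attr(series, "clipped") <- 0L
    return(series)
  }
  clipped <- 0L
  for (ch in c("activity", "light")) {
    x <- series[[ch]]
    m <- mean(x[series$wear], na.rm = TRUE)
    s <- sd(x[series$wear], na.rm = TRUE)
    if (is.na(s) || s == 0) {
      stop("zero-variance channel; cannot normalize", call. = FALSE)
    }
    ref <- reference[[ch]]
    y <- (x - m) / s * ref["sd"] + ref["mean"]
    below <- !is.na(y) & y < 0
    clipped <- clipped + sum(below)
    y[below] <- 0
    series[[ch]] <- as.numeric(y)
  }
  attr(series, "clipped") <- clipped
  series
}
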