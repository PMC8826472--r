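# EpochSeries: one subject's actimetry recording at a fixed epoch length.
# Activity is in device counts per epoch, light in lux; both may be NA.
# `wear` marks epochs judged on-wrist; wear == FALSE implies both channels NA.

#' Construct an epoch series
#'
#' Container for a single subject's actimetry recording: activity counts and
#' light (lux) on a fixed epoch grid, together with a wear mask and a device
#' tag. This is the unit every preprocessing and rhythm-analysis function
#' operates on.
#'
#' @param subject_id character scalar.
#' @param start_time POSIXct (or ISO-8601 string) of the first epoch's start,
#'   interpreted as local wall-clock time.
#' @param epoch_min epoch length in minutes; must divide 1440.
#' @param activity numeric vector of non-negative counts per epoch (NA = missing).
#' @param light numeric vector of non-negative lux per epoch (NA = missing).
#' @param wear logical wear mask; where `FALSE`, both channels are forced to NA.
#' @param device device tag, `"ActTrust"` or `"Actiwatch2"`.
#' @return an object of class `epoch_series`.
#' @export
epoch_series <- function(subject_id, start_time, epoch_min, activity, light,
                         wear = NULL, device = c("Actiwatch2", "ActTrust")) {
  device <- match.arg(device)
  if (is.character(start_time)) {
    start_time <- as.POSIXct(start_time, tz = "UTC")
  }
  if (is.na(start_time)) stop("unparseable start_time", call. = FALSE)
  stopifnot_scalar(epoch_min, "epoch_min", 1, 1440)
  if (1440 %% epoch_min != 0) {
    stop("epoch_min must divide 1440", call. = FALSE)
  }
  n <- length(activity)
  if (length(light) != n) {
    stop("activity and light must have equal length", call. = FALSE)
  }
  if (is.null(wear)) wear <- rep(TRUE, n)
  if (length(wear) != n) stop("wear mask length mismatch", call. = FALSE)
  if (any(activity < 0, na.rm = TRUE) || any(light < 0, na.rm = TRUE)) {
    stop("activity and light must be non-negative", call. = FALSE)
  }
  activity[!wear] <- NA_real_
  light[!wear] <- NA_real_
  structure(
    list(subject_id = as.character(subject_id), start_time = start_time,
         epoch_min = as.integer(epoch_min), activity = as.numeric(activity),
         light = as.numeric(light), wear = as.logical(wear), device = device),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x$activity)
  cat(sprintf("<epoch_series> subject %s, device %s\n", x$subject_id, x$device))
  cat(sprintf("  %d epochs of %d min (%.1f days) from %s\n", n, x$epoch_min,
              n * x$epoch_min / 1440, format(x$start_time, "%Y-%m-%d %H:%M")))
  cat(sprintf("  missing: activity %d, light %d; non-wear epochs: %d\n",
              sum(is.na(x$activity)), sum(is.na(x$light)), sum(!x$wear)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$activity)

# Clock hour (decimal, [0, 24)) of each epoch start.
epoch_clock_hours <- function(series) {
  lt <- as.POSIXlt(series$start_time)
  h0 <- lt$hour + lt$min / 60 + lt$sec / 3600
  (h0 + (seq_along(series$activity) - 1L) * series$epoch_min / 60) %% 24
}

# Hours since the series start, one per epoch.
epoch_elapsed_hours <- function(series) {
  (seq_along(series$activity) - 1L) * series$epoch_min / 60
}

#' Read an actimetry recording from CSV
#'
#' Two device dialects are supported. `ActTrust` files carry columns
#' `DATE/TIME` (`DD/MM/YYYY HH:MM:SS`), `PIM` (activity) and `LIGHT` (lux);
#' `Actiwatch2` files carry `timestamp` (ISO-8601), `activity` and
#' `white_light`. Gaps in the timestamp grid are filled with missing epochs so
#' the returned series is contiguous.
#'
#' @param path CSV file path.
#' @param dialect `"ActTrust"` or `"Actiwatch2"`.
#' @param subject_id optional id; defaults to the file name without extension.
#' @return an [epoch_series].
#' @export
read_actimetry_csv <- function(path, dialect = c("ActTrust", "Actiwatch2"),
                               subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "ActTrust") {
    need <- c("DATE/TIME", "PIM", "LIGHT")
    if (!all(need %in% names(df))) {
      stop("ActTrust file must have columns DATE/TIME, PIM, LIGHT", call. = FALSE)
    }
    ts <- as.POSIXct(df[["DATE/TIME"]], format = "%d/%m/%Y %H:%M:%S", tz = "UTC")
    act <- df[["PIM"]]; lux <- df[["LIGHT"]]
  } else {
    need <- c("timestamp", "activity", "white_light")
    if (!all(need %in% names(df))) {
      stop("Actiwatch2 file must have columns timestamp, activity, white_light",
           call. = FALSE)
    }
    ts <- as.POSIXct(df[["timestamp"]], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    if (anyNA(ts)) ts <- as.POSIXct(df[["timestamp"]], tz = "UTC")
    act <- df[["activity"]]; lux <- df[["white_light"]]
  }
  if (anyNA(ts)) {
    stop(sprintf("row %d: unparseable timestamp", which(is.na(ts))[1]),
         call. = FALSE)
  }
  dt <- as.numeric(diff(ts), units = "mins")
  if (any(dt <= 0)) {
    stop(sprintf("row %d: non-monotone timestamp", which(dt <= 0)[1] + 1L),
         call. = FALSE)
  }
  bad <- which(act < 0 | lux < 0)
  if (length(bad)) {
    stop(sprintf("row %d: negative value", bad[1]), call. = FALSE)
  }
  epoch_min <- if (length(dt)) min(dt) else 10
  if (epoch_min %% 1 != 0 || any(dt %% epoch_min != 0)) {
    stop("timestamps are not on a regular epoch grid", call. = FALSE)
  }
  # place observations on the full grid; unobserved epochs become NA
  idx <- as.integer(round(as.numeric(ts - ts[1], units = "mins") / epoch_min)) + 1L
  n <- idx[length(idx)]
  activity <- rep(NA_real_, n); light <- rep(NA_real_, n)
  activity[idx] <- act; light[idx] <- lux
  epoch_series(subject_id, ts[1], epoch_min, activity, light,
               device = dialect)
}

#' Write an epoch series to the canonical CSV layout
#'
#' Columns: `subject_id, timestamp, epoch_min, activity, light_lux, wear,
#' device` with ISO-8601 timestamps. [read_epoch_series_csv()] is its inverse.
#'
#' @param series an [epoch_series].
#' @param path output file.
#' @export
write_epoch_series_csv <- function(series, path) {
  ts <- series$start_time +
    (seq_along(series$activity) - 1L) * series$epoch_min * 60
  df <- data.frame(
    subject_id = series$subject_id,
    timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
    epoch_min = series$epoch_min,
    activity = series$activity,
    light_lux = series$light,
    wear = as.integer(series$wear),
    device = series$device)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an epoch series from the canonical CSV layout
#' @param path file written by [write_epoch_series_csv()].
#' @return an [epoch_series].
#' @export
read_epoch_series_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  epoch_series(df$subject_id[1],
               as.POSIXct(df$timestamp[1], format = "%Y-%m-%dT%H:%M:%S",
                          tz = "UTC"),
               df$epoch_min[1], df$activity, df$light_lux,
               wear = df$wear == 1L, device = df$device[1])
}
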