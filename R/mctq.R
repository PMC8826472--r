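# MCTQ-derived sleep-timing variables, eligibility rules, and BMI
# categorization (WHO cutoffs).

#' Sleep-timing variables from one MCTQ record
#'
#' Computes sleep durations and mid-sleep times on workdays (MSW) and free
#' days (MSF, the chronotype marker), and social jetlag (SJL) as the absolute
#' shorter-arc difference between the two midpoints on the 24 h clock. All
#' clock arithmetic is circular, so schedules crossing midnight are handled
#' naturally. SJL is also categorized as greater than 1 h, the form used in
#' the regression models.
#'
#' @param record one-row data frame with columns `subject_id`,
#'   `sleep_onset_w`, `sleep_end_w`, `sleep_onset_f`, `sleep_end_f`
#'   ("HH:MM" or decimal hours), plus optional `outdoor_h_w`, `outdoor_h_f`.
#' @return one-row data frame: `MSW`, `MSF` (decimal clock hours), `SD_w`,
#'   `SD_f` (hours), `SJL_h` (absolute hours), `SJL_gt_1h` (logical).
#' @export
sleep_metrics <- function(record) {
  on_w <- parse_clock(record$sleep_onset_w)
  end_w <- parse_clock(record$sleep_end_w)
  on_f <- parse_clock(record$sleep_onset_f)
  end_f <- parse_clock(record$sleep_end_f)
  if (on_w == end_w || on_f == end_f) {
    stop("sleep onset equals sleep end; duration degenerate", call. = FALSE)
  }
  sd_w <- clock_span_h(on_w, end_w)
  sd_f <- clock_span_h(on_f, end_f)
  msw <- (on_w + sd_w / 2) %% 24
  msf <- (on_f + sd_f / 2) %% 24
  sjl <- abs(circ_diff_h(msf, msw))
  data.frame(subject_id = record$subject_id,
             MSW = msw, MSF = msf, SD_w = sd_w, SD_f = sd_f,
             SJL_h = sjl, SJL_gt_1h = sjl > 1,
             outdoor_h_w = if ("outdoor_h_w" %in% names(record))
               record$outdoor_h_w else NA_real_,
             outdoor_h_f = if ("outdoor_h_f" %in% names(record))
               record$outdoor_h_f else NA_real_,
             stringsAsFactors = FALSE)
}

#' BMI and WHO category
#'
#' `bmi = weight / height^2`; categories are half-open intervals:
#' underweight below 18.5, normal `[18.5, 25)`, overweight `[25, 30)`,
#' obese 30 and above.
#'
#' @param weight_kg weight in kilograms.
#' @param height_m height in metres (plausibility-checked).
#' @return data frame with `bmi` (rounded to 4 decimals) and `bmi_category`.
#' @export
bmi_categorize <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0.5) || any(height_m >= 2.5)) {
    stop("implausible anthropometry", call. = FALSE)
  }
  bmi <- round(weight_kg / height_m^2, 4)
  category <- cut(bmi, c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
                  labels = c("underweight", "normal", "overweight", "obese"))
  data.frame(bmi = bmi, bmi_category = as.character(category),
             stringsAsFactors = FALSE)
}

#' Eligibility per the study's exclusion rules
#'
#' A subject is excluded for night-shift work in the previous 6 months, alarm
#' use on work-free days (which invalidates MSF as a chronotype marker), or
#' an underweight BMI. Reason codes accumulate; a subject is eligible only
#' with none.
#'
#' @param subject one-row data frame with `bmi_category`.
#' @param record one-row MCTQ data frame with `night_shift_6mo`, `alarm_f`.
#' @return data frame: `eligible` (logical) and `reasons`
#'   (";"-separated codes among `NIGHT_SHIFT`, `ALARM_FREE`, `UNDERWEIGHT`).
#' @export
apply_exclusions <- function(subject, record) {
  reasons <- character(0)
  if (isTRUE(as.logical(record$night_shift_6mo))) reasons <- c(reasons, "NIGHT_SHIFT")
  if (isTRUE(as.logical(record$alarm_f))) reasons <- c(reasons, "ALARM_FREE")
  if (identical(subject$bmi_category, "underweight")) {
    reasons <- c(reasons, "UNDERWEIGHT")
  }
  data.frame(subject_id = subject$subject_id,
             eligible = length(reasons) == 0L,
             reasons = paste(reasons, collapse = ";"),
             stringsAsFactors = FALSE)
}
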