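# Synthetic cohort generator: actimetry series with controllable
# fragmentation and day-to-day stability, MCTQ records consistent with the
# actimetry, covariates, and BMI categories drawn from a log-link binary
# outcome model with known prevalence ratios. Every downstream stage has a
# recovery test against these ground truths.

#' Parameters of a simulated actimetry recording
#'
#' The default recording emulates the field protocol: 7 days of 10-min epochs
#' of wrist activity counts plus light (lux), with a habitual active window,
#' within-window rest/active bout switching (drives IV), day-level phase
#' jitter (drives 1 - IS), multiplicative lognormal activity noise,
#' state-coupled light with occasional light-at-night events, inserted
#' non-wear zero-runs, and a device gain for the ActTrust brand.
#'
#' @param n_days recording length in days.
#' @param epoch_min epoch length in minutes (must divide 1440).
#' @param active_onset_h,active_offset_h clock hours of the habitual active
#'   window (e.g. 07:00-23:00).
#' @param mean_active,mean_rest mean activity counts per epoch in each state.
#' @param frag_switch_prob per-epoch probability of toggling the within-window
#'   rest/active state.
#' @param phase_jitter_sd_h SD (hours) of day-level phase shifts.
#' @param noise_cv coefficient of variation of multiplicative activity noise.
#' @param light_day_lux,light_night_lux median lux by state.
#' @param light_log_sd lognormal sigma (log10) of lux spread.
#' @param lan_prob probability of a light-at-night event per night.
#' @param nonwear_bouts,nonwear_len_epochs number and length of inserted
#'   non-wear zero-runs.
#' @param device `"Actiwatch2"` or `"ActTrust"`.
#' @param device_gain multiplicative factor applied (last) when the device is
#'   ActTrust.
#' @param mode `"schedule"` (two-state square-wave day), `"cosine"` (noise-free
#'   24 h cosinusoid; calibration), or `"white_noise"` (iid Gaussian counts
#'   offset to be non-negative; calibration).
#' @return list of class `series_params`.
#' @export
series_params <- function(n_days = 7, epoch_min = 10,
                          active_onset_h = 7, active_offset_h = 23,
                          mean_active = 250, mean_rest = 15,
                          frag_switch_prob = 0.12, phase_jitter_sd_h = 0.5,
                          noise_cv = 0.3,
                          light_day_lux = 1000, light_night_lux = 1,
                          light_log_sd = 0.4, lan_prob = 0.2,
                          nonwear_bouts = 1, nonwear_len_epochs = 12,
                          device = c("Actiwatch2", "ActTrust"),
                          device_gain = 2, mode = c("schedule", "cosine",
                                                    "white_noise")) {
  device <- match.arg(device)
  mode <- match.arg(mode)
  stopifnot_scalar(n_days, "n_days", 1)
  stopifnot_scalar(epoch_min, "epoch_min", 1, 1440)
  if (1440 %% epoch_min != 0) stop("epoch_min must divide 1440", call. = FALSE)
  stopifnot_scalar(frag_switch_prob, "frag_switch_prob", 0, 1)
  stopifnot_scalar(mean_active, "mean_active", 1e-9)
  stopifnot_scalar(mean_rest, "mean_rest", 1e-9)
  stopifnot_scalar(device_gain, "device_gain", 1e-9)
  stopifnot_scalar(noise_cv, "noise_cv", 0)
  stopifnot_scalar(phase_jitter_sd_h, "phase_jitter_sd_h", 0)
  stopifnot_scalar(lan_prob, "lan_prob", 0, 1)
  structure(as.list(environment()), class = "series_params")
}

#' Simulate one actimetry recording
#'
#' Reproducible given `seed`; the caller's RNG state is untouched.
#'
#' @param params a [series_params] object.
#' @param seed integer seed.
#' @param subject_id id carried on the series.
#' @param start_time start of the recording (local midnight by default).
#' @return an [epoch_series].
#' @export
simulate_epoch_series <- function(params, seed, subject_id = "sim",
                                  start_time = as.POSIXct("2019-03-04 00:00:00",
                                                          tz = "UTC")) {
  if (!inherits(params, "series_params")) {
    stop("params must be a series_params object", call. = FALSE)
  }
  p <- params
  ep_day <- 1440L %/% p$epoch_min
  n <- as.integer(p$n_days * ep_day)
  with_seed(seed, {
    h <- ((seq_len(n) - 1L) %% ep_day) * p$epoch_min / 60  # clock hour
    if (p$mode == "cosine") {
      mid <- (p$active_onset_h + clock_span_h(p$active_onset_h,
                                              p$active_offset_h) / 2) %% 24
      amp <- (p$mean_active - p$mean_rest) / 2
      mes <- (p$mean_active + p$mean_rest) / 2
      activity <- mes + amp * cos(2 * pi * (h - mid) / 24)
      light <- p$light_night_lux +
        (p$light_day_lux - p$light_night_lux) *
        (1 + cos(2 * pi * (h - mid) / 24)) / 2
    } else if (p$mode == "white_noise") {
      # iid Gaussian offset into positive territory; the variance ratio that
      # defines IV is offset-invariant
      sdev <- p$mean_active * max(p$noise_cv, 0.1)
      activity <- pmax(0, rnorm(n, mean = 10 * sdev, sd = sdev))
      light <- pmax(0, rnorm(n, mean = 10 * sdev, sd = sdev))
    } else {
      day <- (seq_len(n) - 1L) %/% ep_day
      shift <- rnorm(p$n_days, 0, p$phase_jitter_sd_h)[day + 1L]
      hh <- (h - shift) %% 24
      active <- if (p$active_onset_h <= p$active_offset_h) {
        hh >= p$active_onset_h & hh < p$active_offset_h
      } else {
        hh >= p$active_onset_h | hh < p$active_offset_h
      }
      # within-window bout switching: each epoch flips state with prob frag
      flip <- runif(n) < p$frag_switch_prob
      state <- xor(active, flip)
      base <- ifelse(state, p$mean_active, p$mean_rest)
      noise <- if (p$noise_cv > 0) {
        sdlog <- sqrt(log(1 + p$noise_cv^2))
        rlnorm(n, -sdlog^2 / 2, sdlog)
      } else 1
      activity <- base * noise
      lmed <- ifelse(state, p$light_day_lux, p$light_night_lux)
      # light-at-night events: a 1-2 h block of day-level light in the rest span
      for (d in seq_len(p$n_days)) {
        if (runif(1) < p$lan_prob) {
          rest_idx <- which(day == d - 1L & !state)
          if (length(rest_idx) > 3L) {
            len <- sample(6:12, 1L)
            s0 <- sample(rest_idx, 1L)
            lmed[s0:min(s0 + len - 1L, n)] <- p$light_day_lux
          }
        }
      }
      light <- lmed * 10^rnorm(n, 0, p$light_log_sd)
    }
    # insert exact zero-runs (simulated off-wrist)
    if (p$nonwear_bouts > 0 && p$mode == "schedule") {
      for (b in seq_len(p$nonwear_bouts)) {
        s0 <- sample.int(n - p$nonwear_len_epochs, 1L)
        activity[s0:(s0 + p$nonwear_len_epochs - 1L)] <- 0
        light[s0:(s0 + p$nonwear_len_epochs - 1L)] <- 0
      }
    }
    gain <- if (p$device == "ActTrust") p$device_gain else 1
    epoch_series(subject_id, start_time, p$epoch_min,
                 activity * gain, light * gain, device = p$device)
  })
}

#' Parameters of a simulated cohort
#'
#' The outcome model is a log-link binary model on overweight-or-obese:
#' `P(case) = baseline_prev * true_pr_iv^z * true_pr_urban^u * true_pr_female^f`
#' with `z` the subject's designed standardized IV, `u` an indicator of the
#' urban category and `f` of female sex, clipped to `[0, 1]`.
#'
#' @param n_subjects cohort size.
#' @param urbanization_mix proportions over the five urbanization categories
#'   (no electricity, <5 y, >20 y, >=30 y, urban); defaults to the field
#'   cohort's questionnaire mix.
#' @param true_pr_iv prevalence ratio per SD of designed IV.
#' @param true_pr_urban prevalence ratio for the urban category.
#' @param true_pr_female prevalence ratio for female sex.
#' @param baseline_prev outcome prevalence at reference levels.
#' @param p_female proportion of women.
#' @param obese_given_case probability that a case is obese (vs overweight).
#' @param p_acttrust proportion of recordings made with the ActTrust device.
#' @param alarm_free_rate,night_shift_rate rates of the two MCTQ exclusion
#'   flags.
#' @param seed cohort master seed; subject `i` uses `seed + i`.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 200,
                          urbanization_mix = c(no_electricity = 0.117,
                                               lt5y = 0.057, gt20y = 0.333,
                                               ge30y = 0.398, urban = 0.085),
                          true_pr_iv = 1.5, true_pr_urban = 2.0,
                          true_pr_female = 1.5, baseline_prev = 0.2,
                          p_female = 0.6, obese_given_case = 0.48,
                          p_acttrust = 0.5,
                          alarm_free_rate = 0.05, night_shift_rate = 0.03,
                          seed = 1L) {
  if (length(urbanization_mix) != 5L || any(urbanization_mix < 0)) {
    stop("urbanization_mix must be 5 non-negative proportions", call. = FALSE)
  }
  if (abs(sum(urbanization_mix) - 1) > 0.02) {
    stop("urbanization_mix must sum to 1", call. = FALSE)
  }
  urbanization_mix <- urbanization_mix / sum(urbanization_mix)
  for (nm in c("true_pr_iv", "true_pr_urban", "true_pr_female"))
    stopifnot_scalar(get(nm), nm, 1e-9)
  stopifnot_scalar(baseline_prev, "baseline_prev", 0, 1)
  stopifnot_scalar(n_subjects, "n_subjects", 1)
  structure(as.list(environment()), class = "cohort_params")
}

urbanization_levels <- function() {
  c("no_electricity", "lt5y", "gt20y", "ge30y", "urban")
}

#' Simulate covariates, outcome probabilities and BMI for a cohort
#'
#' The covariate/outcome layer of [simulate_cohort()]: no actimetry series are
#' generated, which makes it cheap enough for repeated parameter-recovery
#' simulations. The designed standardized IV (`iv_z`) is the covariate that
#' enters the outcome model; [simulate_cohort()] maps it onto the series
#' generator's fragmentation parameter.
#'
#' @param cparams a [cohort_params] object.
#' @return list with `subjects` (a [SubjectRecord][bmi_categorize] data frame)
#'   and `truth` (designed covariates, probabilities, drawn categories);
#'   a warning is raised if more than 5% of probabilities needed clipping.
#' @export
simulate_outcomes <- function(cparams) {
  if (!inherits(cparams, "cohort_params")) {
    stop("cparams must be a cohort_params object", call. = FALSE)
  }
  cp <- cparams
  with_seed(cp$seed, {
    n <- cp$n_subjects
    id <- sprintf("S%04d", seq_len(n))
    urb <- sample(urbanization_levels(), n, replace = TRUE,
                  prob = cp$urbanization_mix)
    female <- runif(n) < cp$p_female
    age <- round(pmin(92, pmax(16, rnorm(n, 45, 16))))
    iv_z <- rnorm(n)
    prob_raw <- cp$baseline_prev * cp$true_pr_iv^iv_z *
      cp$true_pr_urban^(urb == "urban") * cp$true_pr_female^female
    prob <- pmin(1, prob_raw)
    clip_rate <- mean(prob_raw > 1)
    if (clip_rate > 0.05) {
      warning(sprintf("%.1f%% of outcome probabilities clipped to 1",
                      100 * clip_rate))
    }
    case <- runif(n) < prob
    obese <- case & (runif(n) < cp$obese_given_case)
    category <- ifelse(!case, "normal", ifelse(obese, "obese", "overweight"))
    bmi <- ifelse(category == "normal", runif(n, 18.5, 25),
                  ifelse(category == "overweight", runif(n, 25, 30),
                         runif(n, 30, 40)))
    height <- rnorm(n, 1.65, 0.08)
    weight <- bmi * height^2
    device <- ifelse(runif(n) < cp$p_acttrust, "ActTrust", "Actiwatch2")
    subjects <- data.frame(
      subject_id = id, age = age, sex = ifelse(female, "F", "M"),
      urbanization = urb, height_m = round(height, 3),
      weight_kg = round(weight, 1), self_report_flag = runif(n) < 0.1,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      subject_id = id, iv_z = iv_z, outcome_prob = prob,
      bmi_category = category, device = device,
      clip_rate = clip_rate, stringsAsFactors = FALSE)
    list(subjects = subjects, truth = truth)
  })
}

#' Simulate an MCTQ record consistent with a subject's schedule
#'
#' Sleep falls in the complement of the active window: work-day sleep onset
#' sits near the active offset and sleep end near the active onset; free-day
#' sleep is delayed by the subject's free-day shift, which drives social
#' jetlag.
#'
#' @param truth one-row list/data frame with `subject_id`, `active_onset_h`,
#'   `active_offset_h`, `free_shift_h` (hours by which free-day sleep is
#'   delayed), and logical `alarm_free`, `night_shift`.
#' @param seed integer seed.
#' @param jitter_sd_h SD of reporting noise on each clock time (default 0.25).
#' @return one-row MCTQ data frame (times as "HH:MM").
#' @export
simulate_mctq <- function(truth, seed, jitter_sd_h = 0.25) {
  with_seed(seed, {
    on_w <- (truth$active_offset_h + rnorm(1, 0.5, jitter_sd_h)) %% 24
    end_w <- (truth$active_onset_h + rnorm(1, -0.25, jitter_sd_h)) %% 24
    on_f <- (on_w + truth$free_shift_h + rnorm(1, 0, jitter_sd_h)) %% 24
    end_f <- (end_w + truth$free_shift_h + rnorm(1, 0, jitter_sd_h)) %% 24
    data.frame(
      subject_id = truth$subject_id,
      workdays_per_week = sample(4:6, 1L),
      sleep_onset_w = format_clock(on_w), sleep_end_w = format_clock(end_w),
      alarm_w = runif(1) < 0.5,
      sleep_onset_f = format_clock(on_f), sleep_end_f = format_clock(end_f),
      alarm_f = isTRUE(truth$alarm_free),
      night_shift_6mo = isTRUE(truth$night_shift),
      outdoor_h_w = round(pmax(0, rnorm(1, truth$outdoor_mu_h, 1)), 1),
      outdoor_h_f = round(pmax(0, rnorm(1, truth$outdoor_mu_h * 0.8, 1)), 1),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a full cohort bundle
#'
#' Draws covariates and outcomes via [simulate_outcomes()], then per subject
#' an actimetry recording whose fragmentation tracks the designed
#' standardized IV, and an MCTQ record consistent with the recording's active
#' window. Subject `i` uses seed `cohort seed + i`, so any subject can be
#' regenerated independently.
#'
#' @param cparams a [cohort_params] object.
#' @param with_series generate actimetry series (set FALSE for cheap
#'   covariate-only cohorts).
#' @param series_defaults a [series_params] object used as the template for
#'   every subject's recording.
#' @return list of class `cohort`: `subjects`, `truth`, `mctq` (data frames)
#'   and `series` (named list of [epoch_series], if requested).
#' @export
simulate_cohort <- function(cparams = cohort_params(), with_series = TRUE,
                            series_defaults = series_params()) {
  out <- simulate_outcomes(cparams)
  n <- cparams$n_subjects
  rural_out <- c(no_electricity = 6, lt5y = 5, gt20y = 4, ge30y = 3, urban = 2)
  extra <- with_seed(cparams$seed + 10^6, {
    data.frame(
      active_onset_h = (6 + runif(n, 0, 2)) %% 24,
      active_offset_h = (21 + runif(n, 0, 3)) %% 24,
      free_shift_h = pmax(0, rnorm(n, 0.8, 0.6)),
      alarm_free = runif(n) < cparams$alarm_free_rate,
      night_shift = runif(n) < cparams$night_shift_rate)
  })
  truth <- cbind(out$truth, extra)
  truth$outdoor_mu_h <- unname(rural_out[out$subjects$urbanization])
  # map designed standardized IV onto the fragmentation probability
  truth$frag_switch_prob <- pmin(0.45, pmax(0.01, 0.12 + 0.05 * truth$iv_z))
  mctq <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_mctq(truth[i, ], seed = cparams$seed + i)
  }))
  series <- NULL
  if (with_series) {
    series <- lapply(seq_len(n), function(i) {
      sp <- series_defaults
      sp$active_onset_h <- truth$active_onset_h[i]
      sp$active_offset_h <- truth$active_offset_h[i]
      sp$frag_switch_prob <- truth$frag_switch_prob[i]
      sp$device <- truth$device[i]
      simulate_epoch_series(sp, seed = cparams$seed + i,
                            subject_id = truth$subject_id[i])
    })
    names(series) <- truth$subject_id
  }
  structure(list(subjects = out$subjects, truth = truth, mctq = mctq,
                 series = series, params = cparams), class = "cohort")
}

#' Write a cohort bundle to CSV files
#'
#' Writes `subjects.csv`, `mctq.csv`, `truth.csv` and one canonical actimetry
#' CSV per subject under `dir/actimetry/`.
#'
#' @param cohort a [simulate_cohort()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(cohort$mctq, file.path(dir, "mctq.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(cohort$series)) {
    adir <- file.path(dir, "actimetry")
    dir.create(adir, showWarnings = FALSE)
    for (s in cohort$series) {
      write_epoch_series_csv(s, file.path(adir, paste0(s$subject_id, ".csv")))
    }
  }
  invisible(dir)
}
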