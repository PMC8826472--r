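# End-to-end orchestration: simulate (or read) a cohort, preprocess the
# actimetry, compute rhythm and sleep metrics, run the group comparisons and
# the two prevalence-ratio models, and write all tabular/graphic artifacts
# plus a reproducibility log.

#' Pipeline configuration
#'
#' @param input_dir directory with `subjects.csv`, `mctq.csv` and
#'   `actimetry/*.csv` (canonical layout); NULL to simulate on the fly.
#' @param cparams a [cohort_params] object (simulation mode).
#' @param epoch_min analysis epoch length (minutes).
#' @param nonwear_min_run zero-run length (epochs) that flags non-wear.
#' @param window_days,max_missing_h analysis window length and per-day
#'   missing-data budget.
#' @param reference_device device whose scale is the normalization target.
#' @param boot_B bootstrap replicates for effect-size intervals.
#' @param seed seed for all stochastic stages (bootstrap; and the cohort when
#'   simulating, via `cparams$seed`).
#' @param make_plots write group-profile and per-metric figures (PDF).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, cparams = cohort_params(),
                            epoch_min = 10, nonwear_min_run = 10,
                            window_days = 7, max_missing_h = 4,
                            reference_device = "Actiwatch2",
                            boot_B = 2000, seed = 17, make_plots = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

read_cohort_dir <- function(dir) {
  subjects <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  mctq <- read.csv(file.path(dir, "mctq.csv"), stringsAsFactors = FALSE)
  files <- list.files(file.path(dir, "actimetry"), full.names = TRUE,
                      pattern = "\\.csv$")
  series <- lapply(files, read_epoch_series_csv)
  names(series) <- vapply(series, function(s) s$subject_id, character(1))
  list(subjects = subjects, mctq = mctq, series = series)
}

#' Run the full analysis pipeline
#'
#' Stages: cohort acquisition (simulation or CSV input), actimetry
#' preprocessing (rebin to the analysis epoch, non-wear masking, 7-day window
#' selection, brand normalization), rhythm metrics per subject and channel,
#' MCTQ sleep metrics with eligibility screening, BMI categorization, group
#' comparisons across BMI categories, and two modified Poisson models (an
#' MCTQ model and an actimetry model). Every artifact is written to
#' `out_dir`; re-running with the same config and seed reproduces the outputs
#' byte for byte.
#'
#' @param config a [pipeline_config] object.
#' @param out_dir output directory (created).
#' @return invisibly, a list with all stage outputs (`qc`, `rhythms`,
#'   `sleep`, `analysis`, `comparisons`, `models`, `counts`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("circstrain pipeline run",
                 sprintf("seed: %d", config$seed))
  # stage 1: inputs -----------------------------------------------------------
  if (is.null(config$input_dir)) {
    cohort <- simulate_cohort(config$cparams)
    log_lines <- c(log_lines, sprintf("simulated cohort: n = %d (seed %d)",
                                      config$cparams$n_subjects,
                                      config$cparams$seed))
  } else {
    cohort <- read_cohort_dir(config$input_dir)
    log_lines <- c(log_lines, sprintf("read cohort from %s: n = %d",
                                      config$input_dir, nrow(cohort$subjects)))
  }
  subjects <- cohort$subjects
  n_in <- nrow(subjects)

  # stage 2: preprocessing ----------------------------------------------------
  qc_rows <- list(); kept <- list()
  for (s in cohort$series) {
    if (s$epoch_min != config$epoch_min) s <- rebin(s, config$epoch_min)
    s <- detect_nonwear(s, min_run = config$nonwear_min_run)
    nruns <- attr(s, "nonwear_runs")
    qc <- select_analysis_window(s, n_days = config$window_days,
                                 max_missing_h_per_day = config$max_missing_h)
    qc_rows[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id,
      accepted = !is.null(qc$series),
      reason = ifelse(is.null(qc$series), qc$report$reason, ""),
      days_retained = qc$report$days_retained,
      nonwear_runs = nrow(nruns),
      nonwear_epochs = sum(nruns$length),
      stringsAsFactors = FALSE)
    if (!is.null(qc$series)) kept[[s$subject_id]] <- qc$series
  }
  qc_tab <- do.call(rbind, c(qc_rows, list(make.row.names = FALSE)))
  # brand normalization against the reference-device pool
  if (length(kept)) {
    ref <- brand_reference(kept, config$reference_device)
    kept <- lapply(kept, normalize_brand, reference = ref)
  }
  log_lines <- c(log_lines,
                 sprintf("actimetry: %d in, %d accepted, %d rejected",
                         length(cohort$series), length(kept),
                         length(cohort$series) - length(kept)))

  # stage 3: rhythm metrics ---------------------------------------------------
  rhythms_tab <- do.call(rbind, unlist(lapply(kept, function(s) {
    lapply(c("activity", "light"), function(ch) rhythm_metrics(s, ch))
  }), recursive = FALSE))
  rownames(rhythms_tab) <- NULL

  # stage 4: sleep metrics, BMI, eligibility ----------------------------------
  bmi <- bmi_categorize(subjects$weight_kg, subjects$height_m)
  subjects <- cbind(subjects, bmi)
  sleep_tab <- do.call(rbind, lapply(seq_len(nrow(cohort$mctq)), function(i) {
    rec <- cohort$mctq[i, ]
    sm <- sleep_metrics(rec)
    el <- apply_exclusions(subjects[subjects$subject_id == rec$subject_id, ],
                           rec)
    cbind(sm, el[, c("eligible", "reasons")])
  }))
  rownames(sleep_tab) <- NULL
  n_eligible <- sum(sleep_tab$eligible)
  log_lines <- c(log_lines,
                 sprintf("mctq: %d in, %d eligible, %d excluded (%s)",
                         n_in, n_eligible, n_in - n_eligible,
                         paste(names(table(sleep_tab$reasons[!sleep_tab$eligible])),
                               table(sleep_tab$reasons[!sleep_tab$eligible]),
                               collapse = ", ")))

  analysis <- merge(subjects, sleep_tab, by = "subject_id")
  analysis <- analysis[analysis$eligible, ]
  analysis$urbanization <- factor(analysis$urbanization,
                                  levels = urbanization_levels())
  analysis$sex <- factor(analysis$sex, levels = c("M", "F"))
  analysis$overweight_obese <- as.integer(analysis$bmi_category %in%
                                            c("overweight", "obese"))

  # stage 5: group comparisons ------------------------------------------------
  wide <- stats::reshape(
    rhythms_tab[, c("subject_id", "channel", "IS", "IV", "M10", "L5", "RA",
                    "mesor", "amplitude")],
    idvar = "subject_id", timevar = "channel", direction = "wide", sep = "_")
  comp_data <- merge(analysis, wide, by = "subject_id")
  comp_vars <- c("MSF", "SD_w", "SD_f", "SJL_h",
                 grep("_(activity|light)$", names(wide), value = TRUE))
  comparisons <- compare_by_bmi(comp_data, comp_vars,
                                B = config$boot_B, seed = config$seed)

  # stage 6: regression models ------------------------------------------------
  models <- list()
  models$mctq <- try_model(
    overweight_obese ~ age + sex + urbanization + SJL_gt_1h, analysis)
  if ("IV_activity" %in% names(comp_data) && nrow(comp_data) > 20) {
    comp_data$IV_activity_z <- scale_vec(comp_data$IV_activity)
    comp_data$IV_light_z <- scale_vec(comp_data$IV_light)
    models$actimetry <- try_model(
      overweight_obese ~ age + sex + IV_activity_z, comp_data)
    models$actimetry_final <- try_model(
      overweight_obese ~ age + sex + IV_activity_z + IV_light_z, comp_data)
  }

  # artifacts ------------------------------------------------------------------
  write.csv(qc_tab, file.path(out_dir, "qc_report.csv"), row.names = FALSE)
  write.csv(rhythms_tab, file.path(out_dir, "rhythms.csv"), row.names = FALSE)
  write.csv(sleep_tab, file.path(out_dir, "sleep.csv"), row.names = FALSE)
  write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
            row.names = FALSE)
  reg_tab <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    if (is.null(m)) return(NULL)
    cbind(model = nm, m$table)
  }))
  if (!is.null(reg_tab)) {
    write.csv(reg_tab, file.path(out_dir, "regression.csv"), row.names = FALSE)
  }
  counts <- data.frame(
    stage = c("enrolled", "actimetry_in", "actimetry_accepted",
              "mctq_eligible"),
    n = c(n_in, length(cohort$series), length(kept), n_eligible))
  write.csv(counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
  cfg <- config
  cfg$cparams <- unclass(cfg$cparams)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (isTRUE(config$make_plots) && length(kept)) {
    plot_group_profiles(kept, comp_data, out_dir)
    plot_metric_boxes(comp_data, out_dir)
  }
  writeLines(c(log_lines, "stages complete"), file.path(out_dir, "log.txt"))
  invisible(list(qc = qc_tab, rhythms = rhythms_tab, sleep = sleep_tab,
                 analysis = analysis, comparisons = comparisons,
                 models = models, counts = counts, out_dir = out_dir))
}

scale_vec <- function(x) as.numeric(scale(x))

try_model <- function(formula, data) {
  # small cohorts can leave factor levels empty; drop them so the design
  # stays full rank
  for (v in names(data)) if (is.factor(data[[v]])) data[[v]] <- droplevels(data[[v]])
  out <- tryCatch(fit_modified_poisson(formula, data), error = function(e) {
    message("model skipped: ", conditionMessage(e))
    NULL
  })
  out
}

#' Kruskal-Wallis comparison grid across BMI categories
#'
#' For each variable: the tie-corrected H and p across the BMI categories
#' present, epsilon- and eta-squared with bootstrap intervals, and Dunn-Sidak
#' pairwise results. Degenerate variables (a missing group, constant values)
#' are reported as unavailable rather than dropped.
#'
#' @param data data frame with `bmi_category` and the variables.
#' @param vars character vector of variable names.
#' @param B,seed bootstrap replicates and seed for the effect-size intervals.
#' @return long data frame, one row per variable x pairwise comparison.
#' @export
compare_by_bmi <- function(data, vars, B = 2000, seed = 17) {
  g_all <- factor(data$bmi_category,
                  levels = c("normal", "overweight", "obese"))
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    keep <- !is.na(x) & !is.na(g_all)
    x <- x[keep]; g <- droplevels(g_all[keep])
    base <- data.frame(variable = v, group1 = NA_character_,
                       group2 = NA_character_, H = NA_real_, p = NA_real_,
                       epsilon_sq = NA_real_, eps_lo = NA_real_,
                       eps_hi = NA_real_, eta_sq = NA_real_,
                       z = NA_real_, p_raw = NA_real_, p_sidak = NA_real_,
                       note = "", stringsAsFactors = FALSE)
    if (nlevels(g) < 2L || length(unique(x)) == 1L) {
      base$note <- "unavailable: degenerate groups"
      rows[[length(rows) + 1L]] <- base
      next
    }
    kw <- kruskal_wallis(x, g)
    es <- effect_sizes(x, g, B = B, seed = seed)
    dn <- dunn_sidak(x, g)
    for (j in seq_len(nrow(dn))) {
      r <- base
      r$group1 <- dn$group1[j]; r$group2 <- dn$group2[j]
      r$H <- kw$H; r$p <- kw$p
      r$epsilon_sq <- es$epsilon_sq$est
      r$eps_lo <- es$epsilon_sq$ci[1]; r$eps_hi <- es$epsilon_sq$ci[2]
      r$eta_sq <- es$eta_sq$est
      r$z <- dn$z[j]; r$p_raw <- dn$p_raw[j]; r$p_sidak <- dn$p_sidak[j]
      rows[[length(rows) + 1L]] <- r
    }
    # note missing pairs (e.g. an empty obese group)
    missing_lv <- setdiff(levels(g_all), levels(g))
    for (ml in missing_lv) {
      r <- base
      r$group1 <- ml; r$group2 <- "(any)"
      r$note <- "unavailable: empty group"
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

plot_group_profiles <- function(kept, comp_data, out_dir) {
  grp <- setNames(comp_data$bmi_category, comp_data$subject_id)
  for (ch in c("activity", "light")) {
    profs <- lapply(kept, daily_profile, channel = ch, stat = "mean")
    dfs <- list()
    for (lev in c("normal", "overweight", "obese")) {
      ids <- names(grp)[grp == lev]
      sub <- profs[names(profs) %in% ids]
      if (length(sub) < 2L) next
      gp <- group_profile(sub, "mean")
      dfs[[lev]] <- data.frame(clock_h = gp$clock_h, value = gp$values,
                               se = gp$se, group = lev)
    }
    if (!length(dfs)) next
    df <- do.call(rbind, dfs)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$clock_h, y = .data$value,
                                          colour = .data$group,
                                          fill = .data$group)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           alpha = 0.25, colour = NA) +
      ggplot2::geom_line(linewidth = 0.7) +
      ggplot2::scale_x_continuous(breaks = seq(0, 24, 4)) +
      ggplot2::labs(x = "Clock time (h)",
                    y = if (ch == "activity") "Activity (counts/epoch)"
                        else "Light (lux)",
                    title = sprintf("Mean %s profile by BMI group (+/- SE)", ch)) +
      ggplot2::theme_minimal()
    pdf(file.path(out_dir, sprintf("profile_%s.pdf", ch)), width = 8, height = 4)
    print(p)
    dev.off()
  }
}

plot_metric_boxes <- function(comp_data, out_dir) {
  vars <- grep("^(IS|IV|M10|L5|RA)_(activity|light)$", names(comp_data),
               value = TRUE)
  if (!length(vars)) return(invisible(NULL))
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(metric = v, value = comp_data[[v]],
               group = comp_data$bmi_category)
  }))
  long$group <- factor(long$group, c("normal", "overweight", "obese"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                          fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Rhythm metrics by BMI group") +
    ggplot2::theme_minimal()
  pdf(file.path(out_dir, "metrics_by_bmi.pdf"), width = 9, height = 6)
  print(p)
  dev.off()
  invisible(NULL)
}

#' Render a plain-text summary report for a completed run
#'
#' Collates the run's counts, comparison grid and regression tables into a
#' single human-readable `report.md`.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return path of the report, invisibly.
#' @export
make_report <- function(run_dir) {
  need <- c("counts.csv", "comparisons.csv", "qc_report.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop("run incomplete; missing artifacts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  counts <- read.csv(file.path(run_dir, "counts.csv"))
  comps <- read.csv(file.path(run_dir, "comparisons.csv"),
                    stringsAsFactors = FALSE)
  lines <- c("# Pipeline run summary", "",
             "## Subject flow", "",
             sprintf("- %s: %d", counts$stage, counts$n), "",
             "## Group comparisons (Kruskal-Wallis + Dunn-Sidak)", "")
  fmt_row <- function(r) {
    if (nzchar(r$note)) {
      sprintf("- %s [%s vs %s]: %s", r$variable, r$group1, r$group2, r$note)
    } else {
      sprintf("- %s [%s vs %s]: H = %.2f, p = %.3g, eps2 = %.3f [%.3f, %.3f], p_sidak = %.3g",
              r$variable, r$group1, r$group2, r$H, r$p, r$epsilon_sq,
              r$eps_lo, r$eps_hi, r$p_sidak)
    }
  }
  lines <- c(lines, vapply(seq_len(nrow(comps)),
                           function(i) fmt_row(comps[i, ]), character(1)))
  reg_path <- file.path(run_dir, "regression.csv")
  if (file.exists(reg_path)) {
    reg <- read.csv(reg_path, stringsAsFactors = FALSE)
    lines <- c(lines, "", "## Prevalence-ratio models (modified Poisson, HC0)", "")
    for (m in unique(reg$model)) {
      lines <- c(lines, sprintf("### model: %s", m), "",
                 "term | PR | 95% CI | p", "---|---|---|---")
      sub <- reg[reg$model == m, ]
      lines <- c(lines, sprintf("%s | %.3f | %.3f-%.3f | %.3g",
                                sub$term, sub$PR, sub$ci_lo, sub$ci_hi, sub$p),
                 "")
    }
  }
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
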