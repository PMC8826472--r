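# circstrain

Rest–activity rhythms, light exposure, and body mass index: an analysis
pipeline for wrist actimetry and Munich Chronotype Questionnaire (MCTQ)
data.

## The problem

Disrupted circadian rhythms — fragmented rest–activity patterns, weak
day/night light contrast, irregular sleep timing — are repeatedly linked to
overweight and obesity in epidemiological cohorts. Testing that association
in field data takes a long chain of processing: device-specific actimetry
files must be cleaned of off-wrist periods, trimmed to comparable analysis
windows and normalized across actimeter brands; per-subject rhythm metrics
must be computed; questionnaire sleep variables derived and screened; and the
metric–outcome association estimated with a model whose coefficients read as
prevalence ratios. `circstrain` packages that chain for chronobiology and
epidemiology researchers, together with a synthetic cohort generator with
known ground truth, so every stage of the chain has a recovery test.

## What it computes

**Non-parametric circadian rhythm analysis (NPCRA)** per subject and channel
(activity counts; light in lux), at the 10-min analysis epoch:

- interdaily stability `IS = (N Σ_h (x̄_h − x̄)²) / (p Σ_i (x_i − x̄)²)`,
  the fraction of variance explained by the mean 24-h pattern (0–1; 1 for a
  signal that repeats identically every day);
- intradaily variability `IV = (N Σ (x_i − x_{i−1})²) / ((N−1) Σ (x_i − x̄)²)`,
  the normalized mean-square successive difference (≈0 for a smooth
  sinusoid, ≈2 for Gaussian white noise);
- `M10` / `L5`, the mean over the 10 consecutive highest / 5 consecutive
  lowest hours of the 24-h mean profile (circular windows, wrap-around);
- relative amplitude `RA = (M10 − L5)/(M10 + L5)`, and for light the
  log-offset variant
  `(log10(M10+10) − log10(L5+10))/(log10(M10+10) + log10(L5+10))`;
- single-cosinor mesor, amplitude and acrophase by least squares.

**MCTQ sleep variables**: sleep durations and mid-sleep on workdays (MSW)
and free days (MSF, the chronotype marker), social jetlag
`SJL = |MSF − MSW|` on the circular 24-h clock, and the eligibility screen
(night-shift work, alarm use on free days, underweight BMI).

**Inference**: Kruskal–Wallis comparisons across BMI categories (WHO
cutoffs) with Dunn's post hoc test (Sidak correction) and rank effect sizes
ε² and η² with bootstrap intervals; and modified Poisson regression — a
log-link Poisson fit to the binary overweight/obese outcome with an HC0
sandwich variance — reporting prevalence ratios (PR) with 95% CIs, VIF
collinearity screening, and a Wald test of linearity for continuous terms.

**Synthetic cohorts**: `simulate_cohort()` draws covariates, an outcome from
`P(case) = baseline_prev · PR_iv^z · PR_urban^u · PR_female^f`, actimetry
whose fragmentation tracks the designed standardized IV, and MCTQ records
consistent with each subject's schedule.

## Worked example

```r
library(circstrain)

s <- simulate_epoch_series(series_params(frag_switch_prob = 0.25), seed = 7,
                           subject_id = "S0001")
print(rhythm_metrics(detect_nonwear(s), "activity"), digits = 3)
#>   subject_id  channel   IS  IV M10 M10_onset   L5 L5_onset    RA RA_log mesor
#> 1      S0001 activity 0.29 1.7 194      8.17 58.5        1 0.536     NA   150
#>   amplitude acrophase_h
#> 1        68        14.7
```

(`RA_log` is defined for the light channel only.)

A quarter of the epochs toggled out of the habitual schedule gives a heavily
fragmented recording: IV = 1.7 approaches the white-noise level of 2, and
only 29% of the variance (IS = 0.29) is explained by the mean daily profile.
The subject is most active over the 10 h starting 08:10 (M10 = 194 counts)
and least over the 5 h starting 01:00 (L5 = 58.5), for a day–night contrast
RA = 0.54; the fitted cosinor peaks at 14.7 h.

An end-to-end run on a simulated cohort, and its regression table:

```r
cfg <- pipeline_config(cparams = cohort_params(n_subjects = 150, seed = 42),
                       boot_B = 500)
res <- run_pipeline(cfg, "demo_run")
res$models$actimetry
#> Modified Poisson regression (n = 139, converged after 4 iterations)
#>           term    PR      95% CI       p
#>    (Intercept) 0.318 0.148-0.686 0.00347
#>            age 0.998 0.983-1.013    0.76
#>           sexF 1.284 0.750-2.199   0.363
#>  IV_activity_z 1.339 1.052-1.703  0.0175
```

Each SD of measured activity IV multiplies the prevalence of overweight or
obesity by 1.34 (95% CI 1.05–1.70) in this cohort — an attenuated estimate
of the generator's designed effect of 1.5 per SD of *true* IV, since the
measured metric carries sampling noise. `demo_run/` also contains the QC
report, rhythm and sleep tables, the comparison grid, figures, and a
`report.md` rendered by `make_report("demo_run")`.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/circstrain.R run-all --n 200 --seed 1 --out run
```

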