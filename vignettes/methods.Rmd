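---
title: "Methods: rhythm metrics, sleep variables and prevalence-ratio models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm metrics, sleep variables and prevalence-ratio models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`circstrain` analyses the association between circadian rest–activity and
light-exposure patterns and body mass index. This vignette documents the
models and procedures it implements, the tunable parameters that matter, the
design choices made where several defensible options existed, and what the
synthetic-data tests do and do not demonstrate about field data.

## Actimetry preprocessing

Recordings arrive as timestamped activity counts and lux values in one of
two device dialects (ActTrust; Actiwatch-2) and are placed on a contiguous
epoch grid, with gaps represented as missing epochs. All analyses run at a
10-minute epoch (`epoch_min`, minutes; any divisor of 1440 works, 10 is the
default and the one used throughout the tests). Rebinning sums activity
(counts accumulate) and averages light (lux is an intensity); a coarse bin is
set missing when more than half of its source epochs are missing.

**Non-wear.** Off-wrist periods are detected as maximal runs of at least
`nonwear_min_run = 10` consecutive zero-activity epochs (100 minutes at the
analysis epoch). Both channels are masked across the run: lux recorded by a
pocketed or shelved device is as invalid as its counts. The rule is applied
to the analysis-binned series; applying it before binning would require a
separate threshold in source epochs, and the run length is a configuration
knob for users who prefer that convention.

**Analysis window.** The pipeline analyses `window_days = 7` consecutive
calendar days (midnight-aligned, local wall clock, no daylight-saving
arithmetic) in which every day has at most `max_missing_h = 4` hours of
missing data, the budget read as inclusive. When a recording offers several
qualifying windows the *earliest* is chosen — a deterministic convention so
that re-runs reproduce byte-identical outputs.

**Brand normalization.** Counts and lux scales differ between actimeter
brands. Non-reference recordings are linearly rescaled per channel over wear
epochs so their pooled mean and SD match the reference-device pool
(Actiwatch-2 by default), with negative rescaled values clipped to zero and
counted. Mean/SD matching is the simplest invertible alignment and is
exactly what the downstream metrics require: IS, IV and RA are invariant
under positive affine maps, so normalization affects only the
channel-unit metrics (M10, L5, mesor, amplitude).

## Rhythm metrics

With `p` within-day bins, `N` non-missing epochs, `x̄_h` the across-day mean
of bin `h` and `x̄` the grand mean:

- `IS = (N Σ_h (x̄_h − x̄)²) / (p Σ_i (x_i − x̄)²)`; both sums run over
  available data. A signal repeating identically every 24 h gives exactly 1;
  iid noise over `d` days concentrates near `1/d`. Missing-data imbalance can
  push the ratio slightly above 1; such values are flagged with a warning
  rather than truncated.
- `IV = (N Σ (x_i − x_{i−1})²) / ((N−1) Σ (x_i − x̄)²)`, with differences
  taken only across consecutive non-missing pairs and `N` = pair count + 1,
  so a gap-free series reproduces the classical estimator. A sampled
  noise-free sinusoid gives `2(1 − cos(2πΔ/T)) ≈ (ωΔ)²` (≈0.0019 at 10-min
  epochs), iid Gaussian noise gives ≈2.
- Both metrics refuse series with less than `min_coverage = 80%` of epochs
  present — below that the folded profile is dominated by whichever days
  happen to be observed.
- IS/IV are computed at the analysis epoch (10 min) by default rather than
  re-aggregated to hourly bins; rebinning to 60 min first (`rebin(s, 60)`)
  reproduces the classical hourly definitions when comparability with older
  literature matters. The 10-min figures are the ones all calibration tests
  target.

**M10/L5** scan every circular window of 10 (resp. 5) consecutive hours of
the *mean* 24-h profile — the median profile is refused, because the "mean
wave" definition is what makes M10 ≥ L5 algebraically guaranteed — with
wrap-around across midnight and ties resolved to the earliest onset.
Undefined profile bins (no day contributed) are imputed with the profile mean
and reported; this keeps window means comparable without inventing
structure. `RA = (M10 − L5)/(M10 + L5)`. Light L5 is so often ≈0 lux that RA
saturates near 1; the log-offset variant
`(log10(M10+10) − log10(L5+10))/(log10(M10+10) + log10(L5+10))` spreads that
range and is emitted for the light channel alongside plain RA.

**Cosinor.** `x(t) = M + A cos(2π(t − φ)/24)` is fitted by least squares via
the linear cos/sin parameterization over wear epochs. The acrophase is
reported as the clock hour of the fitted peak (not as negative radians),
matching how field studies phrase "time of peak". Goodness is the fraction
of variance explained, floored at 0 for flat fits.

## Sleep variables and eligibility

All MCTQ clock arithmetic is circular on the 24-h clock: durations are
`(end − onset) mod 24`, midpoints `onset + duration/2`, and social jetlag the
absolute shorter-arc distance `|MSF − MSW|`. The absolute value sidesteps the
two sign conventions in circulation (workday-minus-free vs free-minus-workday);
the regression models only consume the categorized form `SJL > 1 h`, for
which the sign is irrelevant. MSF is the plain free-day midpoint, not the
sleep-debt-corrected MSFsc — the chronotype marker is used descriptively
here, and the correction would entangle it with workday sleep duration.

Exclusions: night-shift work in the previous 6 months, alarm use on
work-free days (it invalidates MSF as a chronotype marker), and underweight
BMI (< 18.5 kg/m²; too rare in the target population to form a group).
Self-reported anthropometry is carried as a flag, not excluded. BMI
categories are half-open WHO intervals — [18.5, 25) normal, [25, 30)
overweight, ≥ 30 obese — so each boundary value belongs to the heavier
category.

## Inference

Variables are compared across the three BMI categories with the
tie-corrected Kruskal–Wallis test (chi-square reference on k−1 df), Dunn's
post hoc z tests from pooled mid-ranks, and Sidak adjustment
`1 − (1 − p)^m` applied within each variable's family of `m = k(k−1)/2`
pairwise comparisons (not across variables). Effect sizes are
`ε² = H(n+1)/(n²−1)` and `η² = (H − k + 1)/(n − k)`, the latter floored at 0
(it is negative for small H), with percentile bootstrap intervals from
resampling subjects with replacement (`boot_B = 2000` by default, seeded).
An empty or constant group renders the comparison "unavailable" rather than
failing the run.

**Modified Poisson.** Associations with the binary overweight/obese outcome
are estimated by a log-link Poisson fit (IRLS) with the HC0 sandwich
covariance: bread `(XᵀWX)⁻¹`, `W = diag(μ̂)`; meat `Σ xᵢxᵢᵀ(yᵢ − μ̂ᵢ)²`.
Exponentiated coefficients are prevalence ratios; intervals are Wald on the
log scale. This estimator is implemented natively rather than through a GLM
wrapper because it is the package's headline model and must be verifiable
against closed forms: on a saturated two-group design the PR equals the
ratio of proportions and the robust SE equals the binomial closed form
`√((1−p₁)/(n₁p₁) + (1−p₀)/(n₀p₀))`, which the tests assert to 1e-8;
`glm(..., family = poisson)` plus `sandwich::vcovHC(type = "HC0")` serves as
an independent cross-check on random designs. VIFs (`1/(1 − R²_j)`) screen
the design, flagging terms above 5. Linearity of a continuous term is probed
by adding quartile-bin indicators to its linear effect and jointly Wald-testing
them with the robust covariance; a rejection recommends categorization (the
route taken for SJL). The quartile-indicator form was chosen over spline
contrasts for interpretability at field-study sample sizes.

Two models are first-class: an MCTQ model (age, sex, urbanization, SJL > 1 h)
on the questionnaire-eligible set, and an actimetry model (age, sex,
standardized activity IV, optionally light IV) on the accepted-recording
set. The urbanization factor uses five categories (no electricity, <5 y,
>20 y, ≥30 y of electricity, urban) with *no electricity* as the reference
level; study reports are not always unambiguous about the reference, so it
is a releveling away for users who prefer another baseline.

## The synthetic cohort generator

The generator exists so that recovery tests, not reproductions of any
particular field cohort, anchor the pipeline. Its defaults emulate a 7-day,
10-min-epoch wrist recording: a habitual active window (07:00–23:00, mean
250 counts/epoch active vs 15 at rest), per-epoch state toggling with
probability `frag_switch_prob = 0.12` (driving IV), day-level phase jitter
with SD 0.5 h (driving IS down), multiplicative lognormal noise with CV 0.3
(counts are non-negative and right-skewed), state-coupled lognormal light
(day median 1000 lux, night 1 lux, spread 0.4 log10 units) with a
light-at-night event on 20% of nights, one inserted 2-h non-wear zero-run,
and a ×2 gain when the device is ActTrust (a pure multiplicative distortion,
the simplest invertible brand effect). Two calibration modes replace the
schedule: a noise-free 24-h cosine (IV ≈ 0, IS = 1) and iid Gaussian counts
offset to be non-negative (IV ≈ 2; the variance ratio is offset-invariant).

Cohort-level defaults: urbanization mix 11.7/5.7/33.3/39.8/8.5% across the
five categories, 60% women, ages ~N(45, 16) truncated to 16–92, designed
prevalence ratios 1.5 per SD of IV, 2.0 for urban residence, 1.5 for female
sex, baseline prevalence 0.2 (chosen so that the log-link probability
rarely needs clipping — the clip rate is monitored and a warning issued
above 5%), and an overweight/obese split of 52/48% among cases. Heights are
~N(1.65, 0.08) m and weight is solved from a BMI drawn uniformly within the
drawn category's interval, since only the category enters the analysis.
Subject `i` draws from seed `cohort_seed + i`, so any subject regenerates
independently. The designed standardized IV maps to the fragmentation
parameter as `frag = 0.12 + 0.05·z` (clamped to [0.01, 0.45]), a monotone
link verified by a seeded Spearman test.

**What passing tests show — and do not.** Recovery of designed prevalence
ratios (within 10% at n = 2000, pooled CI coverage ≈ 95% over 200
replicates) demonstrates that the estimation machinery is correct under the
generator's assumptions: a log-linear outcome model, independent subjects,
schedules with a single active window, and reporting noise that is symmetric
and modest. Field data violate several of these — activity is
autocorrelated within bouts, questionnaires carry systematic biases, the
outcome model is at best an approximation — so the tests certify the
*software*, not the epidemiology. Fitting measured (rather than designed) IV
attenuates effect estimates toward the null, visible in the README example;
that attenuation is a property of noisy exposures, not a defect.

## Numerical choices and problem sizes

Determinism is a design goal throughout: every stochastic stage takes an
explicit seed, simulation helpers restore the caller's RNG state, window and
tie ambiguities resolve to the earliest candidate, and a re-run with the
same configuration reproduces outputs byte for byte. IRLS iterates to a
relative deviance change below 1e-10 (cap 50 iterations); linear predictors
are clamped to ±30 before exponentiation. Degenerate inputs fail loudly:
zero-variance series for IS/IV, all-missing channels for the cosinor,
rank-deficient designs, `M10 + L5 = 0` for RA.

The test suite's simulation sizes — 500 replicates for the white-noise IV
calibration, 200 for CI coverage and cosinor unbiasedness, 2000 null
replicates for the Kruskal–Wallis type-I check, cohorts of 12–50 subjects
for pipeline properties — keep the whole suite in the minutes range on one
CPU while leaving Monte-Carlo error well inside each asserted tolerance.

## Known limitations

The chi-square reference for Kruskal–Wallis is an approximation; at very
small samples (n ≤ 8) it deviates from the exact permutation null by up to
≈0.1 in p, which the test suite measures against a full-enumeration oracle.
The generator does not model sleep architecture, seasonal photoperiod, or
geographic structure among communities; device differences are reduced to a
gain. Quantile mapping as an alternative brand normalization and the MSFsc
chronotype correction are noted in the interfaces but the defaults (moment
matching; plain MSF) are what the acceptance checks exercise.
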