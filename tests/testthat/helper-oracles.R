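# Independent oracles used across the suite. These deliberately take the
# naive route (exhaustive scans, enumeration, closed forms) and never call
# the implementation they check.

# Naive circular window scan: mean over every window of `len_bins`
# consecutive bins (wrapping), returning the extreme value and onset index.
oracle_window_extreme <- function(values, len_bins, which = c("max", "min")) {
  which <- match.arg(which)
  p <- length(values)
  means <- vapply(seq_len(p), function(i) {
    idx <- ((i - 1L) + seq_len(len_bins) - 1L) %% p + 1L
    mean(values[idx])
  }, numeric(1))
  i <- if (which == "max") which.max(means) else which.min(means)
  list(value = means[i], onset = i)
}

# Kruskal-Wallis H from ranks (tie-corrected), for the permutation oracle.
oracle_kw_H <- function(x, g) {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) * sum(tapply(r, g, function(v) length(v) * mean(v)^2)) -
    3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact permutation p-value of the KW test by full enumeration of all
# assignments of the observations to the group sizes (n <= 8).
oracle_kw_perm_p <- function(x, g) {
  g <- factor(g)
  n <- length(x)
  stopifnot(n <= 8)
  perm_list <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  H_obs <- oracle_kw_H(x, g)
  Hs <- vapply(perm_list(seq_len(n)), function(p) oracle_kw_H(x[p], g),
               numeric(1))
  mean(Hs >= H_obs - 1e-9)
}

# Closed forms for the saturated two-group modified Poisson model:
# PR = ratio of proportions; robust SE of log PR from binomial variances.
oracle_two_group_pr <- function(events1, n1, events0, n0) {
  p1 <- events1 / n1
  p0 <- events0 / n0
  list(PR = p1 / p0,
       se_log = sqrt((1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0)))
}

# Small simulated series used by several files.
make_clean_series <- function(seed = 1, n_days = 7, mode = "schedule") {
  simulate_epoch_series(
    series_params(n_days = n_days, mode = mode, nonwear_bouts = 0),
    seed = seed)
}

# Tile one daily pattern over `n_days` as an epoch_series (no missing data).
tile_series <- function(day_values, n_days = 7, epoch_min = 10,
                        subject_id = "tile") {
  epoch_series(subject_id, "2019-03-04 00:00:00", epoch_min,
               rep(day_values, n_days), rep(day_values, n_days))
}
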