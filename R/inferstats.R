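# Group comparisons across BMI categories and prevalence-ratio regression.
#
# The modified Poisson model (log-link Poisson IRLS on a binary outcome with
# an HC0 sandwich variance) is implemented natively: it is the study design's
# headline model and is tested against two-group closed forms.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference distribution on k - 1 degrees
#' of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param x numeric values.
#' @param g group labels (coerced to factor).
#' @return list: `H`, `df`, `p`, `n`, `k`.
#' @export
kruskal_wallis <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(g) == 0L)) stop("empty group", call. = FALSE)
  if (length(unique(x)) == 1L) {
    stop("all values identical; H degenerate", call. = FALSE)
  }
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), df = as.integer(kt$parameter),
       p = kt$p.value, n = length(x), k = nlevels(g))
}

#' Dunn's post hoc test with Sidak correction
#'
#' Pairwise z statistics from pooled mid-ranks with the usual tie correction;
#' two-sided normal p-values are Sidak-adjusted within the family of
#' `m = k(k-1)/2` comparisons: `p_sidak = 1 - (1 - p)^m`.
#'
#' @inheritParams kruskal_wallis
#' @return data frame: `group1`, `group2`, `z`, `p_raw`, `p_sidak`.
#' @export
dunn_sidak <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = levels(g)[pairs[1, ]],
                    group2 = levels(g)[pairs[2, ]],
                    z = NA_real_, p_raw = NA_real_, p_sidak = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[i1] + 1 / ni[i2]))
    z <- if (se > 0) (rbar[i1] - rbar[i2]) / se else 0
    p <- 2 * pnorm(-abs(z))
    out$z[j] <- unname(z)
    out$p_raw[j] <- p
    out$p_sidak[j] <- min(1, 1 - (1 - p)^m)
  }
  out
}

#' Rank effect sizes with bootstrap confidence intervals
#'
#' Epsilon-squared `H (n + 1) / (n^2 - 1)` and eta-squared
#' `(H - k + 1) / (n - k)` (floored at 0) for a Kruskal-Wallis H, with seeded
#' percentile bootstrap intervals obtained by resampling subjects with
#' replacement and recomputing H.
#'
#' @param x numeric values.
#' @param g group labels.
#' @param B bootstrap replicates (default 2000).
#' @param seed bootstrap seed.
#' @param conf confidence level (default 0.95).
#' @return list: `epsilon_sq`, `eta_sq`, each with `est`, `ci` (lo, hi).
#' @export
effect_sizes <- function(x, g, B = 2000, seed = 17, conf = 0.95) {
  g <- factor(g)
  n <- length(x); k <- nlevels(g)
  if (n <= k) stop("n must exceed the number of groups", call. = FALSE)
  kw <- kruskal_wallis(x, g)
  eps <- kw$H * (n + 1) / (n^2 - 1)
  eta <- max(0, (kw$H - k + 1) / (n - k))
  boots <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      gg <- droplevels(g[idx])
      if (nlevels(gg) < 2L || length(unique(x[idx])) == 1L) {
        return(c(NA_real_, NA_real_))
      }
      kb <- suppressWarnings(kruskal.test(x[idx], gg))
      H <- unname(kb$statistic); kk <- nlevels(gg)
      c(H * (n + 1) / (n^2 - 1), max(0, (H - kk + 1) / (n - kk)))
    }, numeric(2))
  })
  a <- (1 - conf) / 2
  ci <- function(v) unname(quantile(v, c(a, 1 - a), na.rm = TRUE))
  list(epsilon_sq = list(est = eps, ci = ci(boots[1, ])),
       eta_sq = list(est = eta, ci = ci(boots[2, ])),
       H = kw$H, n = n, k = k, B = B)
}

# -- modified Poisson ---------------------------------------------------------

#' Modified Poisson regression for prevalence ratios
#'
#' Fits a log-link Poisson model to a binary outcome by iteratively
#' reweighted least squares and reports exponentiated coefficients as
#' prevalence ratios with an HC0 sandwich variance: bread = inverse Fisher
#' information `(X' W X)^-1` with `W = diag(mu)`, meat = the outer product of
#' per-subject score contributions `x_i (y_i - mu_i)`. Wald 95% intervals are
#' formed on the log scale. Variance inflation factors of the non-intercept
#' design columns are attached as a collinearity screen.
#'
#' @param formula model formula; the response must be 0/1 or logical.
#' @param data data frame.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   deviance change.
#' @return object of class `modified_poisson`: data frame `table` (term, PR,
#'   ci_lo, ci_hi, se_log, p, VIF), plus `coef`, `vcov`, `n`, `converged`,
#'   `iterations`.
#' @export
fit_modified_poisson <- function(formula, data, max_iter = 50, tol = 1e-10) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  X <- model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  beta <- c(log(max(mean(y), 1 / n)), rep(0, p - 1))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    eta <- pmax(pmin(eta, 30), -30)  # guard against under/overflow
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    fit <- lm.wfit(X, z, W)
    beta <- fit$coefficients
    dev <- 2 * sum(ifelse(y > 0, y * log(y / exp(pmin(drop(X %*% beta), 30))), 0) -
                     (y - exp(pmin(drop(X %*% beta), 30))))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
    dev_old <- dev
  }
  eta <- pmin(drop(X %*% beta), 30)
  mu <- exp(eta)
  XtWX <- crossprod(X, X * mu)
  if (rcond(XtWX) < 1e-10) {
    stop("information matrix is numerically singular; too few subjects for ",
         "this design", call. = FALSE)
  }
  bread <- solve(XtWX)
  score <- X * (y - mu)
  meat <- crossprod(score)
  V <- bread %*% meat %*% bread
  # V is PSD in exact arithmetic; clip rounding-level negatives on the diagonal
  se <- sqrt(pmax(diag(V), 0))
  zval <- beta / se
  pr <- exp(beta)
  vifs <- if (p > 2) c(NA, vif(X[, -1, drop = FALSE])) else rep(NA_real_, p)
  tab <- data.frame(term = colnames(X), PR = pr,
                    ci_lo = exp(beta - qnorm(0.975) * se),
                    ci_hi = exp(beta + qnorm(0.975) * se),
                    se_log = se, p = 2 * pnorm(-abs(zval)),
                    VIF = vifs, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, coef = beta, vcov = V, n = n,
                 converged = converged, iterations = it,
                 formula = formula),
            class = "modified_poisson")
}

#' @export
print.modified_poisson <- function(x, ...) {
  cat(sprintf("Modified Poisson regression (n = %d, %s after %d iterations)\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  tab <- x$table
  tab$PR <- sprintf("%.3f", tab$PR)
  tab$`95% CI` <- sprintf("%.3f-%.3f", x$table$ci_lo, x$table$ci_hi)
  tab$p <- sprintf("%.3g", x$table$p)
  print(tab[, c("term", "PR", "95% CI", "p")], row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing design column j on the others
#' (with an intercept). Perfect collinearity yields `Inf`.
#'
#' @param X numeric design matrix of non-intercept predictor columns.
#' @param flag_threshold columns with VIF above this are flagged via the
#'   `flagged` attribute (default 5).
#' @return named numeric VIFs with attribute `flagged`.
#' @export
vif <- function(X, flag_threshold = 5) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 predictor columns", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    if (sst == 0) return(NA_real_)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  attr(out, "flagged") <- names(out)[!is.na(out) & out > flag_threshold]
  out
}

#' Wald test of linearity for a continuous regression term
#'
#' Refits the model with quartile-bin indicator terms of `term` added to its
#' linear effect and jointly tests (robust Wald, chi-square) whether the
#' indicators add anything beyond linearity. A significant result recommends
#' categorizing the term, the route the study design took for social jetlag.
#'
#' @param formula base model formula containing `term` linearly.
#' @param data data frame.
#' @param term name of the continuous term to probe.
#' @param alpha significance level used for the recommendation (default 0.05).
#' @return list: `statistic`, `df`, `p`, `nonlinear` (logical), or a
#'   "skipped" result (with a warning) when the term has too few distinct
#'   values to bin.
#' @export
wald_linearity <- function(formula, data, term, alpha = 0.05) {
  x <- data[[term]]
  if (is.null(x)) stop("term not found in data", call. = FALSE)
  qs <- unique(quantile(x, c(0.25, 0.5, 0.75)))
  if (length(unique(x)) < 4L || length(qs) < 3L) {
    warning("too few distinct values to bin; linearity test skipped")
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                nonlinear = NA, skipped = TRUE))
  }
  qbin <- cut(x, c(-Inf, qs, Inf), labels = FALSE)
  data$.qbin <- factor(qbin)
  f2 <- stats::update(formula, . ~ . + .qbin)
  fit <- fit_modified_poisson(f2, data)
  idx <- grep("^\\.qbin", names(fit$coef))
  b <- fit$coef[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V) %*% b)
  df <- length(idx)
  p <- pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, nonlinear = p < alpha,
       skipped = FALSE)
}
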