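# Internal helpers: clock arithmetic and input checks.

#' Parse "HH:MM" clock strings to decimal hours
#'
#' @param x character vector of clock times ("HH:MM" or "HH:MM:SS").
#' @return numeric hours in `[0, 24)`.
#' @keywords internal
parse_clock <- function(x) {
  if (is.numeric(x)) return(x %% 24)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (any(is.na(p)) || length(p) < 2L) {
      stop("invalid clock time; expected HH:MM", call. = FALSE)
    }
    (p[1] + p[2] / 60 + if (length(p) >= 3L) p[3] / 3600 else 0) %% 24
  }, numeric(1))
}

#' Format decimal hours as "HH:MM"
#' @keywords internal
format_clock <- function(h) {
  h <- h %% 24
  mins <- round(h * 60)
  sprintf("%02d:%02d", (mins %/% 60) %% 24, mins %% 60)
}

# Signed shorter-arc difference a - b on the 24 h circle, in (-12, 12].
circ_diff_h <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}

# Duration from clock time `from` to the next occurrence of `to`, in (0, 24].
clock_span_h <- function(from, to) {
  d <- (to - from) %% 24
  ifelse(d == 0, 24, d)
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a scalar in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

# Evaluate `expr` under a private RNG stream; the caller's .Random.seed is
# left untouched so simulation helpers never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}
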