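#' Significance star codes
#'
#' The usual strict-inequality code: `****` for p < 0.0001, `***` for
#' p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise. A p
#' exactly at a boundary maps to the weaker code.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of codes.
#' @export
#' @examples
#' stars(c(0.03, 0.0004, 0.05))
stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p must be in [0, 1]", call. = FALSE)
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 1e-4, "****",
             ifelse(p[ok] < 1e-3, "***",
             ifelse(p[ok] < 1e-2, "**",
             ifelse(p[ok] < 0.05, "*", "ns"))))
  out
}

#' Signed percent change relative to a reference
#'
#' @param reference Reference value (non-zero).
#' @param value New value.
#' @return `100 * (value - reference) / reference`.
#' @export
#' @examples
#' percent_change(1.0, 0.14) # -86
percent_change <- function(reference, value) {
  if (any(reference == 0)) stop("reference must be non-zero", call. = FALSE)
  100 * (value - reference) / reference
}

comparison_row <- function(measure, m1, sem1, n1, m2, sem2, n2, t, df, p,
                           degenerate = FALSE) {
  tibble::tibble(
    measure = measure,
    mean_a = m1, sem_a = sem1, n_a = n1,
    mean_b = m2, sem_b = sem2, n_b = n2,
    t = t, df = df, p = p,
    percent_change = if (m1 != 0) percent_change(m1, m2) else NA_real_,
    stars = stars(p), degenerate = degenerate
  )
}

#' Two-sample comparison of per-cell values
#'
#' Student's pooled-variance two-tailed t-test (the default used to match
#' reported summary statistics; Welch available via `welch = TRUE`),
#' reported together with each group's mean, SEM and n, the percent
#' change of `b` relative to `a`, and the significance star code.
#'
#' @param a,b Numeric vectors of per-cell values (reference group first);
#'   `NA`s are dropped; each group needs n >= 2.
#' @param measure Label for the compared measure.
#' @param welch Use the Welch (unequal-variance) test instead.
#'
#' @return A one-row tibble: `measure`, `mean_a`, `sem_a`, `n_a`,
#'   `mean_b`, `sem_b`, `n_b`, `t`, `df`, `p`, `percent_change`, `stars`,
#'   `degenerate` (TRUE when the pooled variance is zero).
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(1, 2, 3))
compare_groups <- function(a, b, measure = "value", welch = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate: no within-group variance
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(comparison_row(measure, mean(a), 0, length(a),
                          mean(b), 0, length(b),
                          t = if (same) 0 else Inf * sign(mean(b) - mean(a)),
                          df = length(a) + length(b) - 2,
                          p = if (same) 1 else 0, degenerate = TRUE))
  }
  ht <- stats::t.test(b, a, var.equal = !welch)
  comparison_row(measure, mean(a), sem(a), length(a),
                 mean(b), sem(b), length(b),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Two-sample t-test reconstructed from summary statistics
#'
#' Rebuilds each group SD as `sem * sqrt(n)` and applies the
#' pooled-variance two-tailed t formula (Welch optional). Useful for
#' re-checking printed mean +/- SEM results; note the reconstructed p can
#' differ from a printed one when the per-measure n differs from the
#' stated cohort n.
#'
#' @param mean_a,sem_a,n_a Reference-group summary (n >= 2, sem > 0).
#' @param mean_b,sem_b,n_b Comparison-group summary.
#' @inheritParams compare_groups
#' @return A one-row tibble, as [compare_groups()].
#' @export
#' @examples
#' compare_from_summary(12, 3, 14, 35, 5, 37)
compare_from_summary <- function(mean_a, sem_a, n_a, mean_b, sem_b, n_b,
                                 measure = "value", welch = FALSE) {
  if (n_a < 2 || n_b < 2) stop("n must be >= 2 in both groups", call. = FALSE)
  if (sem_a <= 0 || sem_b <= 0) stop("sem must be > 0", call. = FALSE)
  s_a2 <- (sem_a * sqrt(n_a))^2
  s_b2 <- (sem_b * sqrt(n_b))^2
  if (welch) {
    se2 <- s_a2 / n_a + s_b2 / n_b
    t <- (mean_b - mean_a) / sqrt(se2)
    df <- se2^2 / ((s_a2 / n_a)^2 / (n_a - 1) + (s_b2 / n_b)^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * s_a2 + (n_b - 1) * s_b2) / (n_a + n_b - 2)
    t <- (mean_b - mean_a) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  p <- 2 * stats::pt(-abs(t), df)
  comparison_row(measure, mean_a, sem_a, n_a, mean_b, sem_b, n_b, t, df, p)
}

#' Compare two empirical amplitude distributions
#'
#' Two-sample Kolmogorov-Smirnov statistic plus the direction of the
#' shift (sign of the median difference): `"right_shifted"` means group
#' `b` has the higher median.
#'
#' @param a,b Non-empty numeric samples (reference first).
#' @return A one-row tibble: `ks`, `p`, `direction`, `median_a`,
#'   `median_b`.
#' @export
compare_ecdfs <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ht <- suppressWarnings(stats::ks.test(b, a))
  dm <- stats::median(b) - stats::median(a)
  tibble::tibble(
    ks = unname(ht$statistic), p = ht$p.value,
    direction = if (dm > 0) "right_shifted" else if (dm < 0) "left_shifted" else "none",
    median_a = stats::median(a), median_b = stats::median(b)
  )
}
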