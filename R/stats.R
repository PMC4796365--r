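# Exact cohort statistics, implemented from first principles.
#
# The two hypothesis tests used for cohort comparisons are written out
# explicitly (hypergeometric enumeration; rank statistics), rather than
# delegated, so their two-sided conventions are pinned down: Fisher uses
# the "probability at most that of the observed table" rule; the
# Mann-Whitney two-sided p doubles the smaller tail.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities that do not exceed the observed table's probability
#' (with a 1e-7 relative tolerance for ties).
#'
#' @param table 2x2 matrix (or length-4 vector, column-major) of
#'   non-negative counts.
#' @return two-sided p-value. Degenerate margins (a zero row or column
#'   total) give p = 1.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4 || any(x < 0) || any(x != round(x)))
    cc_stop("InvalidTable", "need four non-negative integer counts")
  m <- matrix(x, 2, 2)
  r <- rowSums(m); cs <- colSums(m)
  if (any(r == 0) || any(cs == 0)) return(1)
  # support of the (1,1) cell given fixed margins
  k <- max(0, cs[1] - r[2]):min(r[1], cs[1])
  p <- stats::dhyper(k, r[1], r[2], cs[1])
  p_obs <- stats::dhyper(m[1, 1], r[1], r[2], cs[1])
  sum(p[p <= p_obs * (1 + 1e-7)])
}

#' Mann-Whitney U test
#'
#' U counts, over all (x, y) pairs, the x-greater pairs plus half the
#' ties (midranks). The two-sided p is exact (complete enumeration of
#' rank assignments) when the pooled sample size is at most
#' `exact_max_n` and there are no ties; otherwise a normal approximation
#' with tie correction and (optionally) continuity correction is used.
#'
#' @param x,y numeric samples (nonempty).
#' @param exact_max_n largest pooled n for exact enumeration.
#' @param continuity apply the continuity correction in the normal
#'   approximation.
#' @return list with `U` (statistic for the first sample), `p` and
#'   `method`. Identical pooled values give p = 1.
#' @export
mann_whitney <- function(x, y, exact_max_n = 12L, continuity = TRUE) {
  if (!length(x) || !length(y)) cc_stop("EmptySample", "both samples must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  if (stats::var(pooled) == 0) return(list(U = U, p = 1, method = "degenerate"))
  if (n <= exact_max_n && !ties) {
    # exact null distribution of U by enumeration of rank assignments
    combs <- utils::combn(n, nx)
    u_all <- apply(combs, 2, function(ix) sum(ix) - nx * (nx + 1) / 2)
    lo <- mean(u_all <= U); hi <- mean(u_all >= U)
    p <- min(1, 2 * min(lo, hi))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma <- sqrt(nx * ny / 12 * (n + 1 - tie_corr))
  z <- U - mu
  if (continuity) z <- sign(z) * max(0, abs(z) - 0.5)
  p <- min(1, 2 * stats::pnorm(-abs(z / sigma)))
  list(U = U, p = p, method = "normal")
}

#' Summary statistics: mean, s.d., s.e.m., n
#'
#' The s.e.m. is s.d./sqrt(n) with the (n - 1)-denominator s.d.; for a
#' single value the s.e.m. is undefined (reported as `NA`).
#'
#' @param values nonempty numeric vector.
#' @return list with `mean`, `sd`, `sem`, `n`.
#' @export
summarize_values <- function(values) {
  if (!length(values)) cc_stop("EmptySample", "no values to summarize")
  n <- length(values)
  s <- if (n > 1) stats::sd(values) else NA_real_
  list(mean = mean(values), sd = s,
       sem = if (n > 1) s / sqrt(n) else NA_real_, n = n)
}

# NA-safe variant for cohort tables where a category may be empty.
summarize_or_na <- function(values) {
  if (!length(values)) list(mean = NA_real_, sd = NA_real_, sem = NA_real_, n = 0L)
  else summarize_values(values)
}
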