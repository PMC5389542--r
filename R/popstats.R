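# Population-level summaries and significance tests for per-cell scores.

#' Summarize a vector of per-cell TOS values
#'
#' @param x Numeric vector of scores (nonempty).
#' @return One-row data.frame: `n`, `median_tos` (mean of central two for
#'   even n), `mean_tos`, `sem` (sd with n-1 denominator over sqrt(n); 0
#'   with `sem_defined = FALSE` when n = 1), `fraction_positive` (share
#'   strictly above 0).
#' @export
summarize_tos <- function(x) {
  if (length(x) == 0) stop("cannot summarize an empty score vector")
  n <- length(x)
  sem <- if (n > 1) stats::sd(x) / sqrt(n) else 0
  data.frame(n = n,
             median_tos = stats::median(x),
             mean_tos = mean(x),
             sem = sem,
             sem_defined = n > 1,
             fraction_positive = mean(x > 0))
}

# rank-sum U statistic of sample a against pooled ranks
u_statistic <- function(ranks_a, n1) sum(ranks_a) - n1 * (n1 + 1) / 2

#' Mann-Whitney U test, two-tailed
#'
#' Exact by enumeration of all group assignments when the pooled sample
#' has at most 20 observations (ties handled naturally through mid-ranks
#' of the observed pooled values); otherwise the normal approximation with
#' tie correction and continuity correction. The two-tailed p doubles the
#' smaller tail probability (capped at 1).
#'
#' @param a,b Numeric score vectors (each nonempty).
#' @return p-value.
#' @export
mann_whitney_two_tailed <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples must be nonempty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) return(1)
  rk <- rank(pooled)
  u_obs <- u_statistic(rk[seq_len(n1)], n1)
  n <- n1 + n2
  if (n <= 20) {
    combs <- utils::combn(n, n1)
    u_all <- apply(combs, 2, function(idx) u_statistic(rk[idx], n1))
    p_lo <- mean(u_all <= u_obs)
    p_hi <- mean(u_all >= u_obs)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) return(1)
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sig2)   # continuity-corrected
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Fisher's exact test on a 2x2 table of positive/negative counts
#'
#' Two-tailed hypergeometric exact test comparing the fraction of
#' positive cells (e.g. membrane TOS > 0) between two groups: sums the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's.
#'
#' @param group_a,group_b Integer `c(positive, negative)` counts; each
#'   group total must be >= 1.
#' @return p-value.
#' @export
fisher_exact_fraction_positive <- function(group_a, group_b) {
  stopifnot(length(group_a) == 2, length(group_b) == 2,
            all(c(group_a, group_b) >= 0))
  if (sum(group_a) < 1 || sum(group_b) < 1)
    stop("each group must contain at least one cell")
  x <- group_a[1]
  m <- group_a[1] + group_b[1]        # total positives
  n_a <- sum(group_a); n_b <- sum(group_b)
  support <- max(0, m - n_b):min(m, n_a)
  probs <- stats::dhyper(support, n_a, n_b, m)
  p_obs <- stats::dhyper(x, n_a, n_b, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Welch's t-test, two-tailed
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom. Degenerate inputs: if both groups have zero variance the p is
#' 1 for equal means and 0 otherwise.
#'
#' @param a,b Numeric vectors with at least 2 observations each.
#' @return p-value.
#' @export
welch_t_two_tailed <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("both samples need >= 2 observations")
  v1 <- stats::var(a); v2 <- stats::var(b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(if (mean(a) == mean(b)) 1 else 0)
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t_stat), df)
}
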