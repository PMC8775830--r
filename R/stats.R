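#' Mann-Whitney U test with an exact small-sample path
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test. When both groups have
#' at most `exact_max` observations the null distribution of U is obtained
#' by exhaustive enumeration of all group assignments of the pooled ranks,
#' which is exact even under ties; the two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`. For larger groups the normal
#' approximation with continuity and tie correction is used (the behavior
#' of the standard rank-sum test implementations).
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_max Largest per-group size for which the exact enumeration
#'   is used.
#' @return A list with `statistic` (U for the first group), `p_value`, and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, method = "undefined"))
  }
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  if (n1 <= exact_max && n2 <= exact_max) {
    splits <- utils::combn(N, n1)
    us <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
    return(list(statistic = u, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = u, p_value = 1, method = "normal_approx"))
  }
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u, p_value = p, method = "normal_approx")
}

#' Fold increase between two median burdens
#'
#' Ratio of the median mutation burden in mutant samples to that in
#' wild-type samples. Undefined (NA) when the wild-type median is zero.
#'
#' @param median_mutant Median burden of the mutant group.
#' @param median_wild Median burden of the wild-type group.
#' @return The ratio, or `NA` if `median_wild` is zero.
#' @examples
#' round(fold_increase(4002, 336), 1) # 11.9
#' @export
fold_increase <- function(median_mutant, median_wild) {
  if (!is.finite(median_wild) || median_wild == 0) return(NA_real_)
  median_mutant / median_wild
}

# Odds ratio of a 2x2 table (a = both, b = first only, c = second only,
# d = neither), with the Haldane-Anscombe 0.5 correction applied only when
# a zero cell is present.
odds_ratio_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}
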