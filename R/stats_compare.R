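# Ranking-comparison statistics: Friedman test across task pairs,
# Wilcoxon signed-rank post-hoc comparisons, Bonferroni correction.

#' Friedman rank test across conditions
#'
#' Rank-based test for differences between `k` related conditions measured
#' on `n` participants (rows). Within-row ties receive average ranks; the
#' chi-square statistic uses the general tie-corrected form
#' `(k-1) * sum_j (R_j - n(k+1)/2)^2 / (sum_ij r_ij^2 - n k (k+1)^2 / 4)`
#' with `df = k - 1`. A matrix of constant rows (no information) yields a
#' statistic of 0 and p = 1.
#'
#' @param perf Numeric matrix, participants x conditions (e.g. peak GMAC
#'   per participant for each of the 10 task pairs); no missing cells.
#' @return List with `chi2`, `df` and `p`.
#' @export
#' @examples
#' m <- matrix(runif(90), 9, 10)
#' friedman_test(m)$df   # 9
friedman_test <- function(perf) {
  perf <- as.matrix(perf)
  if (any(!is.finite(perf))) stop_mt("performance matrix has missing cells")
  n <- nrow(perf)
  k <- ncol(perf)
  if (n < 2 || k < 2) stop_mt("need at least 2 participants and 2 conditions")
  r <- t(apply(perf, 1, rank))
  rj <- colSums(r)
  num <- (k - 1) * sum((rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  chi2 <- if (den <= 0) 0 else num / den
  list(chi2 = chi2, df = k - 1,
       p = stats::pchisq(chi2, df = k - 1, lower.tail = FALSE))
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Paired two-sided test. Zero differences are dropped; ties among the
#' absolute differences receive average ranks with the corresponding
#' variance correction; the standardized statistic uses a 0.5 continuity
#' correction toward the null mean. `Z` is negative when `y` tends to
#' exceed `x` (swapping the arguments negates `Z` and leaves `p`
#' unchanged).
#'
#' @param x,y Paired numeric vectors of equal length; at least 5 non-zero
#'   differences must remain.
#' @return List with `Z`, `p`, `n` (pairs after zero removal) and `W` (sum
#'   of positive-difference ranks).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop_mt("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_mt("all differences are zero; the test is undefined")
  if (n < 5) stop_mt("need at least 5 non-zero differences (have %d)", n)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) stop_mt("degenerate rank variance; the test is undefined")
  delta <- w - mu
  z <- if (delta == 0) 0 else (delta - sign(delta) * 0.5) / sqrt(sigma2)
  list(Z = z, p = min(1, 2 * stats::pnorm(-abs(z))), n = n, W = w)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_comparisons Number of comparisons (>= 1); all unordered pairs
#'   of the 10 task pairs give 45.
#' @return `alpha / n_comparisons`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 45)   # 0.0011...
bonferroni_threshold <- function(alpha, n_comparisons) {
  if (!(alpha > 0 && alpha < 1)) stop_mt("alpha must lie in (0, 1)")
  if (n_comparisons < 1) stop_mt("n_comparisons must be >= 1")
  alpha / n_comparisons
}

#' Pairwise post-hoc comparison of task-pair performance
#'
#' Runs Wilcoxon signed-rank tests for every unordered pair of conditions
#' in the performance matrix and flags significance at the
#' Bonferroni-corrected level `alpha / choose(k, 2)`.
#'
#' @param perf Numeric matrix, participants x conditions, with condition
#'   names as column names.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame with one row per comparison: `pair_a`, `pair_b`,
#'   `Z`, `p`, `significant`; the threshold is attached as attribute
#'   `"threshold"`.
#' @export
compare_task_pairs <- function(perf, alpha = 0.05) {
  perf <- as.matrix(perf)
  k <- ncol(perf)
  if (is.null(colnames(perf))) colnames(perf) <- sprintf("cond%d", seq_len(k))
  idx <- utils::combn(k, 2)
  thr <- bonferroni_threshold(alpha, ncol(idx))
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    a <- idx[1, j]
    b <- idx[2, j]
    res <- wilcoxon_signed_rank(perf[, a], perf[, b])
    data.frame(pair_a = colnames(perf)[a], pair_b = colnames(perf)[b],
               Z = res$Z, p = res$p, significant = res$p < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}
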