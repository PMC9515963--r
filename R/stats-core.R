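## Statistical primitives shared by every stage. These are implemented from
## first principles (exact enumeration where feasible) and cross-checked in
## the test suite against both brute-force oracles and base R.

test_result <- function(statistic, p_value, method, degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 degenerate = degenerate),
            class = "sf_test")
}

#' @export
print.sf_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g%s\n", x$method, x$statistic,
              x$p_value, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

## Exact null distribution of the Mann-Whitney U statistic (no ties):
## count subsets S of {1..N}, |S| = n_a, by rank sum, via the classic
## 0/1-knapsack DP. U = ranksum - n_a(n_a+1)/2.
u_exact_counts <- function(n_a, n_b) {
  n_tot <- n_a + n_b
  max_sum <- sum((n_b + 1L):n_tot)
  ## dp[k+1, s+1] = number of k-subsets of processed ranks with sum s
  dp <- matrix(0, nrow = n_a + 1L, ncol = max_sum + 1L)
  dp[1L, 1L] <- 1
  for (r in seq_len(n_tot)) {
    kmax <- min(r, n_a)
    for (k in kmax:1L) {
      cols <- (r + 1L):(max_sum + 1L)
      dp[k + 1L, cols] <- dp[k + 1L, cols] + dp[k, cols - r]
    }
  }
  min_sum <- n_a * (n_a + 1L) / 2
  dp[n_a + 1L, (min_sum + 1L):(max_sum + 1L)]  # indexed by U = 0..n_a*n_b
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration of the U null distribution when `length(a)*length(b)
#' <= 400` and the data are tie-free; otherwise the normal approximation
#' with tie and continuity corrections. Reported statistic is U for the
#' first sample.
#'
#' @param a,b numeric vectors (each length >= 1).
#' @return an `sf_test` with fields `statistic`, `p_value`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_value  # exact 1/3
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) fail("both samples must be non-empty")
  if (any(!is.finite(c(a, b)))) fail("non-finite values in Mann-Whitney input")
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && n_a * n_b <= 400L) {
    counts <- u_exact_counts(n_a, n_b)
    total <- sum(counts)
    lo <- sum(counts[seq_len(u + 1L)]) / total            # P(U <= u)
    hi <- sum(counts[(u + 1L):length(counts)]) / total    # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    return(test_result(u, p, "mann_whitney_exact"))
  }
  n_tot <- n_a + n_b
  mu <- n_a * n_b / 2
  tie_tab <- table(c(a, b))
  tie_term <- sum(tie_tab^3 - tie_tab) / (n_tot * (n_tot - 1))
  sigma2 <- n_a * n_b / 12 * ((n_tot + 1) - tie_term)
  if (sigma2 <= 0) return(test_result(u, 1, "mann_whitney_normal", degenerate = TRUE))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)  # continuity correction never pushes past the mean
  test_result(u, min(1, 2 * stats::pnorm(-z)), "mann_whitney_normal")
}

## log hypergeometric pmf for a 2x2 table with fixed margins
lhyper <- function(x, m, n, k) {
  lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Conditional on both margins; the two-sided p-value sums hypergeometric
#' probabilities of all tables no more probable than the observed one
#' (relative tolerance 1e-12 for probability ties).
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return an `sf_test`; statistic is the odds-ratio numerator cell.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) fail("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab))) {
    fail("Fisher's exact test requires non-negative integer counts")
  }
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  if (m + n == 0) return(test_result(NA_real_, 1, "fisher_exact", degenerate = TRUE))
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  lp <- lhyper(support, m, n, k)
  lobs <- lhyper(x, m, n, k)
  keep <- lp <= lobs + 1e-12 * abs(lobs) + 1e-12
  p <- min(1, sum(exp(lp[keep])))
  test_result(x, p, "fisher_exact")
}

#' Welch's two-sample t test (two-sided)
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' Both groups constant and equal is flagged degenerate (p = 1).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return an `sf_test`.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) fail("Welch t needs n >= 2 per group")
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    return(test_result(0, 1, "welch_t", degenerate = TRUE))
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  test_result(t_stat, min(1, 2 * stats::pt(-abs(t_stat), df)), "welch_t")
}

#' Pearson's chi-squared test of independence
#'
#' @param tab r x c matrix of non-negative counts.
#' @return an `sf_test` with (r-1)(c-1) degrees of freedom.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) fail("chi-square requires non-negative counts")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  keep_r <- rs > 0; keep_c <- cs > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  rs <- rs[keep_r]; cs <- cs[keep_c]
  if (nrow(tab) < 2L || ncol(tab) < 2L || n == 0) {
    return(test_result(0, 1, "chi_square", degenerate = TRUE))
  }
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  test_result(stat, stats::pchisq(stat, df, lower.tail = FALSE), "chi_square")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA passed through).
#' @return adjusted p-values in the input order, capped at 1.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
#' @export
benjamini_hochberg <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) fail("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(pv[o] * m / seq(m, 1)))
  out[ok][o] <- adj
  out
}

#' Cohen's d standardized mean difference
#'
#' `(mean(a) - mean(b)) / s_pooled` with (n-1)-weighted pooled variance.
#' By the package's sign convention the first argument is the stoma group,
#' so negative d means depletion with a stoma.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return a single number, or `NA` (with a warning) when the pooled SD is 0.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) fail("Cohen's d needs n >= 2 per group")
  n_a <- length(a); n_b <- length(b)
  sp2 <- ((n_a - 1) * stats::var(a) + (n_b - 1) * stats::var(b)) / (n_a + n_b - 2)
  if (sp2 == 0) {
    warning("pooled SD is zero; Cohen's d undefined", call. = FALSE)
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}
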