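test_that("Mann-Whitney exact path matches enumeration of label assignments", {
  ## a = {1,2}, b = {3,4}: U = 0, two-sided p = 1/3
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)
  ## identical multisets give p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  ## brute-force oracle: enumerate all C(n, n_a) group assignments
  set.seed(11)
  for (rep in 1:10) {
    n_a <- sample(2:4, 1); n_b <- sample(2:4, 1)
    x <- sample(1000, n_a + n_b) + stats::runif(n_a + n_b) # tie-free
    a <- x[seq_len(n_a)]; b <- x[-seq_len(n_a)]
    u_stat <- function(idx) {
      sum(rank(x)[idx]) - length(idx) * (length(idx) + 1) / 2
    }
    obs <- u_stat(seq_len(n_a))
    all_u <- apply(utils::combn(n_a + n_b, n_a), 2, u_stat)
    mu <- n_a * n_b / 2
    p_oracle <- mean(abs(all_u - mu) >= abs(obs - mu))
    expect_equal(mann_whitney_u(a, b)$p_value, p_oracle, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximation agrees with a permutation estimate", {
  set.seed(21)
  a <- rnorm(30); b <- rnorm(30, 0.4)
  p <- mann_whitney_u(a, b)$p_value
  x <- c(a, b); rk <- rank(x)
  mu <- 30 * 30 / 2
  obs <- abs(sum(rk[1:30]) - 30 * 31 / 2 - mu)
  perm <- replicate(50000, {
    idx <- sample.int(60, 30)
    abs(sum(rk[idx]) - 30 * 31 / 2 - mu)
  })
  expect_lt(abs(p - mean(perm >= obs)), 0.02)
})

test_that("Mann-Whitney matches base R on exact and tied instances", {
  set.seed(31)
  for (rep in 1:10) {
    a <- sample(100, 6) + 0.25; b <- sample(100, 8) + 0.5
    expect_equal(mann_whitney_u(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    at <- sample(5, 20, TRUE); bt <- sample(5, 25, TRUE)
    expect_equal(mann_whitney_u(at, bt)$p_value,
                 suppressWarnings(stats::wilcox.test(at, bt)$p.value),
                 tolerance = 1e-9)
  }
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / choose(20, 10))
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  set.seed(41)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Welch t and chi-square behave on degenerate and calibrated input", {
  r <- welch_t(rep(2, 5), rep(2, 7))
  expect_true(r$degenerate)
  tab <- outer(c(10, 20), c(3, 7)) / 10  # expected == observed
  r2 <- chi_square(tab)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  set.seed(51)
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(12, 1, 2)
    expect_equal(welch_t(a, b)$p_value, stats::t.test(a, b)$p.value,
                 tolerance = 1e-12)
    tab <- matrix(rpois(6, 20), 2)
    expect_equal(chi_square(tab)$p_value,
                 suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
                 tolerance = 1e-12)
  }
  ## type-I error calibration at alpha = 0.05
  set.seed(61)
  rej <- mean(replicate(1000, welch_t(rnorm(10), rnorm(10))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 0.01 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("Benjamini-Hochberg matches the hand step-up and its properties", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(71)
  for (rep in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))          # never decreases a p-value
    q <- 0.2
    bonf <- which(stats::p.adjust(p, "bonferroni") < q)
    expect_true(all(bonf %in% which(adj < q)))  # BH rejects a superset
  }
})

test_that("Cohen's d uses pooled SD and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(1, 5, 9), c(1, 5, 9)), 0)
  set.seed(81)
  a <- rnorm(9); b <- rnorm(14, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_warning(d0 <- cohens_d(rep(1, 3), rep(1, 4)), "pooled SD")
  expect_true(is.na(d0))
})
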