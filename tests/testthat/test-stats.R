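test_that("fisher_exact matches direct hypergeometric enumeration", {
  set.seed(123)
  # all 2x2 tables with small totals, then random larger ones
  for (N in 2:12) {
    for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
      d <- N - a - b - cc
      if (a + b == 0 || cc + d == 0) next
      p <- fisher_exact(matrix(c(a, b, cc, d), 2, 2, byrow = TRUE))$p_value
      expect_equal(p, oracle_fisher_2x2(a, b, cc, d), tolerance = 1e-12)
    }
  }
  for (i in 1:300) {
    tb <- matrix(sample(0:12, 4, replace = TRUE), 2, 2)
    if (any(rowSums(tb) == 0)) next
    expect_equal(fisher_exact(tb)$p_value,
                 oracle_fisher_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-12)
  }
})

test_that("fisher_exact agrees with stats::fisher.test on r x 2 tables", {
  set.seed(5)
  for (i in 1:40) {
    r <- sample(2:4, 1)
    tb <- matrix(sample(0:9, 2 * r, replace = TRUE), nrow = r)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisher_exact(tb)$p_value, stats::fisher.test(tb)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("fisher_exact is invariant under row and column swaps", {
  set.seed(6)
  for (i in 1:25) {
    tb <- matrix(sample(1:10, 4, replace = TRUE), 2, 2)
    p <- fisher_exact(tb)$p_value
    expect_equal(fisher_exact(tb[2:1, ])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact(tb[, 2:1])$p_value, p, tolerance = 1e-12)
    expect_true(p > 0 && p <= 1)
  }
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)
  zero <- fisher_exact(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(zero$p_value, 1)
  expect_match(zero$method, "zero margin")
})

test_that("proportion differences are oriented group2 minus group1", {
  pd <- proportion_difference(1, 14, 7, 13)
  expect_equal(pd$estimate, 100 * (7 / 13 - 1 / 14))
  expect_equal(round(pd$estimate, 1), 46.7)
  expect_equal(round(proportion_difference(10, 14, 13, 13)$estimate, 1), 28.6)
  expect_equal(proportion_difference(5, 10, 5, 10)$estimate, 0)
  nc <- proportion_difference(1, 14, 7, 13, method = "newcombe")
  expect_true(nc$ci_low < nc$estimate, nc$estimate < nc$ci_high)
  expect_error(proportion_difference(3, 0, 1, 5))
})

test_that("rank-sum p-values: identity, tiny exact case, enumeration oracle", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(wilcoxon_rank_sum(x, x + 0)$p_value, 1, tolerance = 1e-9)
  r <- wilcoxon_rank_sum(c(1, 2), c(10, 11))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_match(r$method, "exact")
  set.seed(21)
  for (i in 1:20) {
    a <- round(runif(sample(3:8, 1)), 6)
    b <- round(runif(sample(3:8, 1)) + runif(1, -0.3, 0.3), 6)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, oracle_wilcox_p(a, b),
                 tolerance = 1e-9)
  }
  # ties force the normal approximation branch
  tied <- wilcoxon_rank_sum(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_match(tied$method, "approximation")
})

test_that("shifted distributions are detected with high power", {
  set.seed(42)
  hits <- mean(replicate(40, {
    x <- rlnorm(30); y <- rlnorm(30) * 3
    wilcoxon_rank_sum(x, y)$p_value < 0.05
  }))
  expect_gt(hits, 0.9)
})

test_that("Hodges-Lehmann equals the brute-force pairwise-difference median", {
  expect_equal(hodges_lehmann(c(1, 2, 3), c(4, 5, 7))$estimate, 3)
  expect_equal(hodges_lehmann(c(1, 2), c(1, 2))$estimate, 0)
  set.seed(14)
  for (i in 1:30) {
    x <- rnorm(sample(2:30, 1)); y <- rnorm(sample(2:30, 1), mean = 1)
    hl <- hodges_lehmann(x, y)
    brute <- median(sapply(y, function(yy) yy - x))
    expect_equal(hl$estimate, brute, tolerance = 1e-12)
    expect_true(hl$ci_low <= hl$estimate && hl$estimate <= hl$ci_high)
  }
  # shift equivariance
  x <- rnorm(10)
  expect_equal(hodges_lehmann(x, x + 2.5)$estimate, 2.5, tolerance = 1e-12)
})

test_that("Lin's CCC: identity, hand-checked value, Pearson relations", {
  x <- c(1, 5, 2, 8, 3)
  expect_equal(lin_ccc(x, x)$estimate, 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$estimate, 4 / 7)
  set.seed(33)
  for (i in 1:25) {
    a <- rnorm(12); b <- rnorm(12)
    expect_lte(abs(lin_ccc(a, b)$estimate), abs(cor(a, b)) + 1e-12)
  }
  # equal means and variances: CCC reduces to Pearson r
  a <- rnorm(15)
  b <- sample(a)  # same multiset: identical mean and variance
  expect_equal(lin_ccc(a, b)$estimate, cor(a, b), tolerance = 1e-12)
  expect_error(lin_ccc(rep(2, 5), rep(2, 5)), "undefined")
})

test_that("bootstrap CIs are seeded, stable and honest about degeneracy", {
  x <- rep(5, 20)
  bc <- bootstrap_ci(function(a, b) mean(a), x, x, n_resamples = 200, seed = 3)
  expect_equal(bc$ci_low, 5); expect_equal(bc$ci_high, 5)
  set.seed(1); n <- 27
  tru <- rnorm(n, 7, 2); r1 <- tru + rnorm(n, 0, 0.4); r2 <- tru + rnorm(n, 0, 0.4)
  ccc_stat <- function(a, b) lin_ccc(a, b)$estimate
  b1 <- bootstrap_ci(ccc_stat, r1, r2, seed = 10)
  b1b <- bootstrap_ci(ccc_stat, r1, r2, seed = 10)
  expect_identical(b1[c("ci_low", "ci_high")], b1b[c("ci_low", "ci_high")])
  expect_true(b1$ci_low <= b1$estimate && b1$estimate <= b1$ci_high)
  b2 <- bootstrap_ci(ccc_stat, r1, r2, seed = 11)
  expect_lt(abs(b1$ci_low - b2$ci_low), 0.05)
  expect_lt(abs(b1$ci_high - b2$ci_high), 0.05)
  # undefined on too many resamples -> error
  expect_error(bootstrap_ci(function(a, b) stop("nope"), r1, r2,
                            n_resamples = 100, seed = 1), "undefined")
})

test_that("median and IQR follow the documented quantile rule", {
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  expect_equal(median_iqr(1:9)[["median"]], 5)
  expect_equal(median_iqr(c(6, 6, 7, 7, 7, 8, 8)),
               c(median = 7, q1 = 6, q3 = 8))
})
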