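test_that("Mann-Whitney: closed-form cases and doubling convention", {
  r <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)  # 2 of 6 assignments as extreme, doubled
  expect_identical(r$method, "exact")

  same <- mann_whitney_exact(c(5, 1, 3), c(3, 1, 5))
  expect_equal(same$p_value, 1)   # no separation: capped at 1

  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney exact p equals the pair-counting enumeration oracle", {
  set.seed(42)
  for (i in 1:12) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    x <- sample(1:6, m, replace = TRUE)  # replacement forces ties
    y <- sample(1:6, n, replace = TRUE)
    expect_equal(mann_whitney_exact(x, y)$p_value, oracle_mw_p(x, y),
                 tolerance = 1e-12,
                 label = sprintf("case %d (m=%d, n=%d)", i, m, n))
  }
  # tie-free case agrees with the reference implementation's exact path
  x <- c(1.2, 3.4, 2.2, 5.1, 0.4); y <- c(2.9, 6.2, 4.4, 7.1)
  expect_equal(mann_whitney_exact(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney invariances: symmetry and monotone transforms", {
  set.seed(7)
  x <- rnorm(8); y <- rnorm(6, 1)
  p_xy <- mann_whitney_exact(x, y)$p_value
  expect_equal(mann_whitney_exact(y, x)$p_value, p_xy, tolerance = 1e-12)
  expect_equal(mann_whitney_exact(exp(x), exp(y))$p_value, p_xy,
               tolerance = 1e-12)
  expect_equal(mann_whitney_exact(atan(x), atan(y))$p_value, p_xy,
               tolerance = 1e-12)
})

test_that("Mann-Whitney switches to a tie-corrected normal approximation", {
  set.seed(11)
  x <- rnorm(20); y <- rnorm(18, 0.8)
  r <- mann_whitney_exact(x, y)  # combined n = 38 > 25
  expect_identical(r$method, "asymptotic")
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Wilcoxon signed-rank: closed forms, zeros, and enumeration oracle", {
  r <- wilcoxon_signed_rank_exact(rep(0, 5), c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 15)
  expect_equal(r$p_value, 2 / 32)  # all differences positive, n = 5

  expect_error(wilcoxon_signed_rank_exact(1:4, 1:4), "all differences are zero")
  expect_error(wilcoxon_signed_rank_exact(1:3, 1:2), "differ in length")

  # zero differences are dropped before ranking
  rz <- wilcoxon_signed_rank_exact(c(0, 0, 1, 2, 3), c(0, 0, 2, 4, 6))
  expect_equal(rz$n, 3L)

  set.seed(99)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    d <- sample(-4:4, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_signed_rank_exact(d)$p_value
    expect_equal(got, oracle_wsr_p(d), tolerance = 1e-12,
                 label = sprintf("case %d (n=%d)", i, n))
  }
})

test_that("Wilcoxon: swapping before/after preserves p, Pratt handles zeros", {
  set.seed(13)
  b <- rnorm(9); a <- b + rnorm(9, 0.5)
  r1 <- wilcoxon_signed_rank_exact(b, a)
  r2 <- wilcoxon_signed_rank_exact(a, b)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$statistic + r2$statistic, r1$n * (r1$n + 1) / 2)

  d <- c(0, 1, 2, -1, 3)
  drop <- wilcoxon_signed_rank_exact(d, zero_method = "drop")
  pratt <- wilcoxon_signed_rank_exact(d, zero_method = "pratt")
  expect_equal(drop$n, pratt$n)
  expect_gt(pratt$statistic, drop$statistic)  # zero inflates ranks under Pratt
})

test_that("Wilcoxon asymptotic path matches the reference beyond the bound", {
  set.seed(5)
  b <- rnorm(30); a <- b + rnorm(30, 0.3)
  r <- wilcoxon_signed_rank_exact(b, a)
  expect_identical(r$method, "asymptotic")
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Spearman: monotone extremes, tie-aware rho, exact and t p-values", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(spearman_cor(x, sqrt(x))$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)

  set.seed(31)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(spearman_cor(x, y)$rho, cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  xt <- sample(1:4, 9, replace = TRUE); yt <- sample(1:4, 9, replace = TRUE)
  expect_equal(spearman_cor(xt, yt)$rho, cor(xt, yt, method = "spearman"),
               tolerance = 1e-12)

  # exact permutation path vs literal n! oracle (n <= 6) and reference exact
  for (i in 1:6) {
    set.seed(300 + i)
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(spearman_cor(x, y)$p_value, oracle_spearman_p(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_cor(x, y)$p_value,
                 cor.test(x, y, method = "spearman", exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }

  # beyond the bound: t approximation
  set.seed(77)
  x <- rnorm(21); y <- x + rnorm(21)
  r <- spearman_cor(x, y)
  expect_identical(r$method, "t-approximation")
  rho <- r$rho
  expect_equal(r$p_value, 2 * pt(-abs(rho * sqrt(19 / (1 - rho^2))), 19),
               tolerance = 1e-12)

  # invariance under strictly monotone transforms of either variable
  expect_equal(spearman_cor(exp(x), y)$rho, rho, tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "n >= 3")
})

test_that("Bonferroni adjustment and decisions", {
  r <- bonferroni_adjust(c(0.01, 0.04), alpha = 0.05)
  expect_equal(r$p_adjusted, c(0.02, 0.08))
  expect_identical(r$reject, c(TRUE, FALSE))
  expect_equal(bonferroni_adjust(0.2)$p_adjusted, 0.2)  # m = 1: identity
  # adjusted p is monotone non-decreasing in the family size
  p <- c(0.001, 0.02, 0.3)
  for (m in 3:6) {
    expect_true(all(bonferroni_adjust(p, m = m)$p_adjusted <=
                      bonferroni_adjust(p, m = m + 1)$p_adjusted))
  }
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "family size")
})
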