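# independent enumeration oracles, written differently from the
# implementation (expand.grid / combn based)

perms_via_grid <- function(n) {
  g <- do.call(expand.grid, rep(list(seq_len(n)), n))
  as.matrix(g[apply(g, 1, function(r) length(unique(r)) == n), ])
}

test_that("spearman rho hits the monotone extremes", {
  expect_equal(spearman_test(1:4, c(10, 20, 30, 40))$statistic, 1)
  expect_equal(spearman_test(1:4, c(40, 30, 20, 10))$statistic, -1)
  r <- spearman_test(1:5, rep(3, 5))
  expect_true(is.na(r$statistic))
  expect_match(r$note, "constant")
})

test_that("small-sample spearman p equals full enumeration", {
  set.seed(31)
  for (k in 1:5) {
    x <- sample(100, 5)
    y <- sample(100, 5)
    r <- spearman_test(x, y)
    expect_true(r$exact_flag)
    perms <- perms_via_grid(5)
    rx <- rank(x); ry <- rank(y)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    oracle <- sum(abs(rhos) >= abs(r$statistic) - 1e-12) / 120
    expect_identical(r$p_value, oracle)
  }
  # ties or n > 8 fall back to the t approximation
  big <- spearman_test(1:20, rnorm(20))
  expect_false(big$exact_flag)
})

test_that("signed-rank p is exact by sign-flip enumeration", {
  # six strictly positive differences: V = 21, one-sided 1/64
  w <- paired_wilcoxon(rep(0, 6), 1:6)
  expect_true(w$exact_flag)
  expect_identical(w$p_value, 2 / 64)
  # two-sided symmetry under swapping the arms
  set.seed(5)
  x <- rnorm(9); y <- rnorm(9, 0.8)
  expect_equal(paired_wilcoxon(x, y)$p_value,
               paired_wilcoxon(y, x)$p_value)
  # matches wilcox.test exact p when there are no tied |differences|
  x2 <- c(1.1, 2.3, 0.7, 5.2, 3.3, 2.8, 4.1, 0.2)
  y2 <- x2 + c(0.9, -1.2, 2.2, 0.8, -1.45, 1.6, -0.1, 1.3)
  expect_equal(paired_wilcoxon(x2, y2)$p_value,
               stats::wilcox.test(y2, x2, paired = TRUE,
                                  exact = TRUE)$p.value)
  # zero differences are dropped; all-zero is degenerate
  d <- paired_wilcoxon(1:5, 1:5)
  expect_true(is.na(d$p_value))
  expect_match(d$note, "degenerate")
  expect_equal(paired_wilcoxon(c(1, 2, 0), c(1, 5, 4))$n, 2)
})

test_that("two-group ranks use exact Mann-Whitney at small n", {
  g <- rank_group_test(list(c(1, 2, 3), c(10, 11, 12)))
  expect_true(g$exact_flag)
  expect_identical(g$p_value, 2 / choose(6, 3))
  # identical groups are null
  same <- rank_group_test(list(c(5, 6, 7, 8), c(5, 6, 7, 8)))
  expect_gte(same$p_value, 0.99)
  # agreement with wilcox.test exact enumeration
  set.seed(41)
  a <- rnorm(5); b <- rnorm(6, 1)
  expect_equal(rank_group_test(list(a, b))$p_value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
  expect_error(rank_group_test(list(1:3, numeric())), "empty group")
})

test_that("two-group Kruskal-Wallis equals the Mann-Whitney approximation", {
  set.seed(43)
  a <- rnorm(20); b <- rnorm(25, 0.6)
  mw <- rank_group_test(list(a, b))
  kw <- stats::kruskal.test(list(a, b))
  expect_false(mw$exact_flag)
  expect_lt(abs(mw$p_value - kw$p.value), 1e-6)
  # > 2 groups: chi-square approximation
  k3 <- rank_group_test(list(rnorm(10), rnorm(10), rnorm(10, 1)))
  expect_equal(k3$method, "kruskal_wallis")
  expect_true(k3$p_value >= 0 && k3$p_value <= 1)
})

test_that("rank statistics are invariant to monotone transforms", {
  set.seed(47)
  x <- rexp(15); y <- x + rnorm(15, 0, 0.3)
  f <- function(v) log(v - min(v) + 1)
  expect_equal(spearman_test(x, y)$statistic,
               spearman_test(f(x), f(y))$statistic)
  a <- rexp(10); b <- rexp(12, 0.5)
  expect_equal(rank_group_test(list(a, b))$statistic,
               rank_group_test(list(f(c(a, b))[1:10],
                                    f(c(a, b))[11:22]))$statistic)
})

test_that("paired mean difference carries the closed-form t interval", {
  pd <- paired_mean_difference_ci(rep(0, 5), 1:5)
  half <- stats::qt(0.975, 4) * stats::sd(1:5) / sqrt(5)
  expect_equal(pd$mean_difference, 3)
  expect_equal(pd$ci_low, 3 - half)
  expect_equal(pd$ci_high, 3 + half)
  expect_equal(pd$n_pairs, 5)
  # identical arms: zero difference inside the interval
  pid <- paired_mean_difference_ci(1:6, 1:6)
  expect_equal(pid$mean_difference, 0)
  expect_true(pid$ci_low <= 0 && 0 <= pid$ci_high)
  # raising the level never narrows the interval
  set.seed(11)
  y <- rnorm(8, 2)
  a95 <- paired_mean_difference_ci(rep(0, 8), y, level = 0.95)
  a99 <- paired_mean_difference_ci(rep(0, 8), y, level = 0.99)
  expect_gte(a99$ci_high - a99$ci_low, a95$ci_high - a95$ci_low)
  expect_error(paired_mean_difference_ci(1, 2), "2 complete pairs")
})

test_that("logistic odds ratios reduce to the 2x2 cross product", {
  out <- c(rep(TRUE, 30), rep(FALSE, 70))
  pred <- c(rep(1, 20), rep(0, 10), rep(1, 25), rep(0, 45))
  or <- logistic_or_pcr(out, pred)
  expect_lt(abs(or$or_per_unit - (20 * 45) / (25 * 10)), 1e-6)
  expect_true(or$converged)
  expect_true(or$ci_low <= or$or_per_unit &&
              or$or_per_unit <= or$ci_high)
  # OR per k units is the per-unit OR to the k-th power
  set.seed(53)
  x <- rnorm(80)
  y <- runif(80) < stats::plogis(0.5 * x)
  o1 <- logistic_or_pcr(y, x, unit_scale = 1)
  o10 <- logistic_or_pcr(y, x, unit_scale = 10)
  expect_equal(o10$or_per_unit, o1$or_per_unit^10, tolerance = 1e-8)
  expect_error(logistic_or_pcr(rep(TRUE, 10), rnorm(10)), "single class")
  expect_error(logistic_or_pcr(y, rep(1, 80)), "constant")
  # perfect separation is flagged
  sep <- logistic_or_pcr(c(rep(FALSE, 10), rep(TRUE, 10)),
                         c(rnorm(10, -5), rnorm(10, 5)))
  expect_false(sep$converged)
})
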