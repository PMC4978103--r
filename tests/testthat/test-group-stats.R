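test_that("summaries use the sample SEM", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(summarize_values(rep(5, 4))$sem, 0)
  expect_error(summarize_values(3), "at least 2")
  expect_equal(summarize_values(c(1, NA, 3))$n, 2)
})

test_that("SEM of resamples concentrates at sigma/sqrt(n) (Monte Carlo)", {
  set.seed(5)
  n <- 7
  sems <- replicate(2000, summarize_values(stats::rnorm(n, 0.46, 0.1))$sem)
  # E[sd] = c4 * sigma for Gaussian samples; the SEM inherits that factor
  c4 <- sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  expect_equal(mean(sems), c4 * 0.1 / sqrt(n), tolerance = 0.01)
})

test_that("identical groups are not significantly different", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  cr <- compare_groups(x, x)
  expect_false(cr$significant)
  expect_gt(cr$p_value, 0.9)
})

test_that("a large separated-mean comparison is significant", {
  set.seed(8)
  cr <- compare_groups(stats::rnorm(200, 0, 1), stats::rnorm(200, 1, 1))
  expect_true(cr$significant)
  expect_lt(cr$p_value, 1e-10)
})

test_that("the normality screen routes to the rank test", {
  set.seed(13)
  a <- stats::rexp(15)^3                 # heavily skewed
  b <- stats::rexp(15)^3 + 5
  cr <- compare_groups(a, b)
  expect_equal(cr$test_used, "wilcoxon_rank")
  set.seed(1)
  norm <- compare_groups(stats::rnorm(10), stats::rnorm(10))
  expect_equal(norm$test_used, "t_test")
})

test_that("comparison is symmetric in the two groups", {
  set.seed(21)
  a <- stats::rnorm(7, 0.46, 0.1); b <- stats::rnorm(6, 0.38, 0.1)
  c1 <- compare_groups(a, b); c2 <- compare_groups(b, a)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
  expect_equal(c1$mean_a - c1$mean_b, -(c2$mean_a - c2$mean_b))
})

test_that("tiny groups fall back to the rank test with a warning", {
  expect_warning(cr <- compare_groups(c(1, 2), c(3, 4)), "n < 3")
  expect_equal(cr$test_used, "wilcoxon_rank")
})

test_that("under the null the rejection rate sits at the nominal level", {
  set.seed(31)
  rej <- 0L
  for (i in 1:2000) {
    cr <- compare_groups(stats::rnorm(7), stats::rnorm(6))
    if (cr$significant) rej <- rej + 1L
  }
  expect_gte(rej / 2000, 0.03)
  expect_lte(rej / 2000, 0.07)
})
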