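test_that("welch_t reproduces the hand-computed example", {
  out <- welch_t(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  # diff -1, SE = sqrt(2.5/5 + 2.5/5) = 1, Satterthwaite df = 8
  expect_equal(out$statistic, -1)
  expect_equal(out$df, 8)
  expect_equal(out$p_value, 2 * pt(-1, 8))
})

test_that("welch_t agrees with t.test on continuous data", {
  set.seed(61)
  for (i in 1:10) {
    x <- rgamma(20 + i, 2)
    y <- rgamma(25, 1.5) + 0.2
    mine <- welch_t(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("welch_t degenerate rules: constant groups", {
  expect_equal(welch_t(rep(2, 5), rep(2, 5))$p_value, 1)
  expect_equal(welch_t(rep(2, 5), rep(2, 5))$statistic, 0)
  expect_equal(welch_t(rep(2, 5), rep(3, 5))$p_value, 0)
  # a sample against itself is never rejected
  set.seed(62)
  x <- rnorm(10)
  expect_equal(welch_t(x, x)$statistic, 0)
  expect_equal(welch_t(x, x)$p_value, 1)
})

test_that("yuen at zero trim reproduces welch exactly", {
  set.seed(63)
  for (i in 1:10) {
    x <- rgamma(15, 1); y <- rgamma(18, 2)
    w <- welch_t(x, y); u <- yuen_trimmed_t(x, y, gamma = 0)
    # same algebra, different evaluation order: agreement to round-off
    expect_equal(w$statistic, u$statistic, tolerance = 1e-12)
    expect_equal(w$df, u$df, tolerance = 1e-12)
    expect_equal(w$p_value, u$p_value, tolerance = 1e-12)
  }
})

test_that("yuen trims symmetric outliers: equal 20%-trimmed means give t = 0", {
  # trimmed mean of (0,1,2,3,100) at gamma = 0.2 is 2; so is that of the
  # contaminated mirror sample
  out <- yuen_trimmed_t(c(0, 1, 2, 3, 100), c(-100, 1, 2, 3, 4), gamma = 0.2)
  expect_equal(out$statistic, 0)
  # identical groups up to permutation -> p = 1
  set.seed(64)
  x <- rnorm(20)
  out <- yuen_trimmed_t(x, sample(x), gamma = 0.2)
  expect_equal(out$p_value, 1)
  expect_error(yuen_trimmed_t(1:4, 1:4, gamma = 0.6), "gamma")
})

test_that("mann_whitney U matches brute-force pair counting and wilcox.test", {
  set.seed(65)
  for (i in 1:8) {
    x <- sample(0:5, 12, replace = TRUE)   # heavy ties on purpose
    y <- sample(0:6, 15, replace = TRUE)
    mine <- mann_whitney(x, y)
    expect_equal(mine$statistic, u_stat_bruteforce(x, y))
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("mann_whitney edge cases", {
  # complete separation
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  # all values identical
  expect_equal(mann_whitney(rep(1, 5), rep(1, 5))$p_value, 1)
})

test_that("mean_diff_ci has the stated width and is centred on the difference", {
  set.seed(66)
  x <- rnorm(30); y <- rnorm(30)
  ci <- mean_diff_ci(x, y)
  expect_equal(ci$point, mean(x) - mean(y))
  expect_equal(ci$upper - ci$lower, 2 * qnorm(0.975) * ci$se)
  ci0 <- mean_diff_ci(x, x)
  expect_equal(ci0$point, 0)
  expect_equal(ci0$upper, -ci0$lower)
})

test_that("mean_diff_ci capture rate is near nominal for normal data", {
  set.seed(67)
  hits <- replicate(2000, {
    ci <- mean_diff_ci(rnorm(50), rnorm(50))
    ci$lower < 0 && ci$upper > 0
  })
  expect_lt(abs(mean(hits) - 0.95), 3 * sqrt(0.95 * 0.05 / 2000) + 0.01)
})

test_that("cohens_d_ci follows the printed standard-error formula", {
  set.seed(68)
  # construct samples with d exactly 0.5 at n = 50
  x <- rnorm(50); x <- (x - mean(x)) / sd(x)
  y <- x + 0.5
  out <- cohens_d_ci(y, x)
  expect_equal(out$point, 0.5, tolerance = 1e-12)
  expect_equal(out$se, sqrt(2 / 50 + 0.25 / 200), tolerance = 1e-12)
  expect_equal(out$se, 0.20310, tolerance = 1e-4)
  # affine invariance
  out2 <- cohens_d_ci(3 * y + 1, 3 * x + 1)
  expect_equal(out2$point, out$point, tolerance = 1e-12)
  # zero mean difference: d = 0, SE = sqrt(2/n)
  out3 <- cohens_d_ci(x, x + rnorm(50, 0, 1e-9))
  expect_equal(out3$se, sqrt(2 / 50), tolerance = 1e-4)
  # undefined when both variances vanish
  expect_false(cohens_d_ci(rep(1, 5), rep(1, 5))$defined)
})

test_that("tost declares equivalence consistently with the (1-2a) CI", {
  set.seed(69)
  theta <- 0.4
  for (i in 1:40) {
    x <- rnorm(30, 0, 1); y <- rnorm(30, 0.1 * (i %% 4), 1)
    eq <- tost(x, y, theta, alpha = 0.05)$equivalent
    w <- cfesim:::welch_se(x, y)
    crit <- qt(0.95, w$df)
    ci_in <- (w$diff - crit * w$se) > -theta && (w$diff + crit * w$se) < theta
    expect_identical(eq, ci_in)
  }
})

test_that("tost limiting behaviour", {
  set.seed(70)
  x <- rnorm(20)
  expect_true(tost(x, x + rnorm(20, 0, 0.1), threshold = 100)$equivalent)
  expect_false(tost(x, x + 50, threshold = 1)$equivalent)
  # size property: true difference exactly at +theta is declared equivalent
  # at most alpha of the time
  eqs <- replicate(1500, tost(rnorm(40), rnorm(40, 0.5), 0.5)$equivalent)
  expect_lt(mean(eqs), 0.05 + 3 * sqrt(0.05 * 0.95 / 1500))
})
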