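test_that("anova_oneway matches aov on random data", {
  set.seed(71)
  for (i in 1:6) {
    g <- lapply(1:3, function(j) rgamma(10 + j, j))
    mine <- anova_oneway(g)
    d <- data.frame(y = unlist(g), f = factor(rep(1:3, times = lengths(g))))
    ref <- summary(aov(y ~ f, d))[[1]]
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(mine$df, c(ref$Df[1], ref$Df[2]))
  }
})

test_that("kruskal_wallis matches kruskal.test including tie correction", {
  set.seed(72)
  for (i in 1:6) {
    g <- lapply(1:3, function(j) sample(0:4, 12, replace = TRUE))
    mine <- kruskal_wallis(g)
    ref <- kruskal.test(g)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  # three identical groups
  g <- rep(list(c(1, 2, 3)), 3)
  expect_equal(kruskal_wallis(g)$statistic, 0)
})

test_that("anova_2x2 matches the linear-model decomposition", {
  set.seed(73)
  for (i in 1:5) {
    cells <- lapply(1:4, function(j) rnorm(8, mean = j %% 3))
    mine <- anova_2x2(cells)
    d <- data.frame(y = unlist(cells),
                    A = factor(rep(c(1, 1, 2, 2), each = 8)),
                    B = factor(rep(c(1, 2, 1, 2), each = 8)))
    ref <- anova(lm(y ~ A * B, d))
    expect_equal(mine$A$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$B$statistic, ref$`F value`[2], tolerance = 1e-10)
    expect_equal(mine$AB$statistic, ref$`F value`[3], tolerance = 1e-10)
    expect_equal(mine$AB$p_value, ref$`Pr(>F)`[3], tolerance = 1e-10)
  }
})

test_that("additive cell means give an exactly zero interaction", {
  # cell means (0, 1, 2, 3) decompose into two main effects with no
  # interaction; identical within-cell noise keeps the means exact
  noise <- c(-0.5, 0.5, -0.25, 0.25)
  cells <- lapply(c(0, 1, 2, 3), function(m) m + noise)
  out <- anova_2x2(cells)
  expect_equal(out$AB$statistic, 0)
  expect_gt(out$A$statistic, 0)
})

test_that("anova_2x2 balanced fixture matches a hand computation", {
  cells <- list(c(1, 3), c(2, 4), c(5, 7), c(8, 10))
  # cell means 2,3,6,9; grand 5; SS_A = 4*((2.5-5)^2+(7.5-5)^2) = 50
  # SS_B = 4*((4-5)^2+(6-5)^2) = 8; SS_cells = 2*(9+4+1+16) = 60 -> SS_AB = 2
  # SS_within = 4 cells * 2 = 8, df2 = 4, MSW = 2
  out <- anova_2x2(cells)
  expect_equal(out$A$statistic, 50 / 2)
  expect_equal(out$B$statistic, 8 / 2)
  expect_equal(out$AB$statistic, 2 / 2)
})

test_that("SRH uses the rank variance: untied SS_total equals (N^3 - N)/12", {
  set.seed(74)
  cells <- lapply(1:4, function(j) runif(6) + j)  # no ties a.s.
  r <- rank(unlist(cells))
  N <- length(r)
  expect_equal(sum((r - mean(r))^2), (N^3 - N) / 12)
  # and the chi-square referral uses df 1 per effect
  out <- srh_test(cells)
  expect_equal(out$A$df, 1)
  expect_equal(out$A$p_value,
               pchisq(out$A$statistic, 1, lower.tail = FALSE))
})

test_that("SRH statistics decompose the rank sums of squares", {
  set.seed(75)
  cells <- lapply(1:4, function(j) sample(0:3, 6, replace = TRUE))
  out <- srh_test(cells)
  r <- rank(unlist(cells))
  rc <- split(r, rep(1:4, each = 6))
  d <- cfesim:::ss_2x2(rc)
  ms <- sum((r - mean(r))^2) / (length(r) - 1)
  expect_equal(out$A$statistic, unname(d$ss["A"]) / ms)
  expect_equal(out$AB$statistic, unname(d$ss["AB"]) / ms)
})

test_that("degenerate all-constant designs retain the null", {
  g <- rep(list(rep(1, 5)), 3)
  expect_equal(anova_oneway(g)$p_value, 1)
  cells <- rep(list(rep(2, 4)), 4)
  expect_equal(anova_2x2(cells)$A$p_value, 1)
  expect_equal(srh_test(cells)$AB$p_value, 1)
})
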