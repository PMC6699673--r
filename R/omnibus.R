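## Multi-group members of the battery: one-way F, Kruskal-Wallis, balanced
## 2x2 ANOVA and its rank-based analogue (Scheirer-Ray-Hare).

#' One-way analysis of variance
#'
#' Standard F-test for equality of group means.  Zero within-group variance
#' everywhere is degenerate: p = 1 when the group means also agree, p = 0
#' otherwise.
#'
#' @param groups list of numeric samples.
#' @param alpha significance level.
#' @return a `"cfe_test"` record with `df = c(df1, df2)`.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  n <- lengths(groups)
  if (any(n < 2)) stop("each group needs at least 2 observations", call. = FALSE)
  N <- sum(n)
  gm <- vapply(groups, mean, numeric(1))
  grand <- sum(n * gm) / N
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(new_test_outcome(0, c(df1, df2), 1, alpha, "anova_oneway"))
    return(new_test_outcome(Inf, c(df1, df2), 0, alpha, "anova_oneway"))
  }
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  new_test_outcome(f, c(df1, df2), p, alpha, "anova_oneway")
}

#' Kruskal-Wallis rank test
#'
#' Chi-square approximation with tie correction.  All values identical
#' across groups gives statistic 0 and p = 1.
#'
#' @param groups list of numeric samples.
#' @param alpha significance level.
#' @return a `"cfe_test"` record.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(unlist(groups, use.names = FALSE))
  idx <- rep(seq_len(k), n)
  rbar <- tapply(r, idx, mean)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  tie_tab <- tabulate(match(r, unique(r)))
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (C <= 0) return(new_test_outcome(0, k - 1, 1, alpha, "kruskal_wallis"))
  H <- H / C
  p <- stats::pchisq(H, k - 1, lower.tail = FALSE)
  new_test_outcome(H, k - 1, p, alpha, "kruskal_wallis")
}

## Balanced 2x2 sums of squares from the four cell samples, cells ordered
## A1B1, A1B2, A2B1, A2B2.  Under balance all ANOVA types coincide.
ss_2x2 <- function(cells) {
  n <- lengths(cells)
  if (length(cells) != 4 || length(unique(n)) != 1)
    stop("need four balanced cells (A1B1, A1B2, A2B1, A2B2)", call. = FALSE)
  n <- unname(n[1])
  if (n < 2) stop("each cell needs at least 2 observations", call. = FALSE)
  m <- vapply(cells, mean, numeric(1))
  grand <- mean(m)
  mA <- c(mean(m[1:2]), mean(m[3:4]))
  mB <- c(mean(m[c(1, 3)]), mean(m[c(2, 4)]))
  ss_a <- 2 * n * sum((mA - grand)^2)
  ss_b <- 2 * n * sum((mB - grand)^2)
  ss_cells <- n * sum((m - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_within <- sum(vapply(cells, function(g) sum((g - mean(g))^2), numeric(1)))
  list(ss = c(A = ss_a, B = ss_b, AB = ss_ab), ss_within = ss_within,
       n = n, N = 4 * n)
}

#' Balanced 2x2 factorial ANOVA
#'
#' F-tests for the two main effects and the interaction, with sums of
#' squares computed from cell means (types coincide in the balanced
#' design).
#'
#' @param cells list of four numeric samples in the order A1B1, A1B2, A2B1,
#'   A2B2, all the same size.
#' @param alpha significance level.
#' @return list of three `"cfe_test"` records named `A`, `B`, `AB`.
#' @export
anova_2x2 <- function(cells, alpha = 0.05) {
  d <- ss_2x2(cells)
  df2 <- d$N - 4
  out <- lapply(seq_along(d$ss), function(i) {
    if (d$ss_within == 0) {
      if (d$ss[i] == 0)
        return(new_test_outcome(0, c(1, df2), 1, alpha, "anova_2x2"))
      return(new_test_outcome(Inf, c(1, df2), 0, alpha, "anova_2x2"))
    }
    f <- d$ss[i] / (d$ss_within / df2)
    new_test_outcome(f, c(1, df2), stats::pf(f, 1, df2, lower.tail = FALSE),
                     alpha, "anova_2x2")
  })
  names(out) <- names(d$ss)
  out
}

#' Scheirer-Ray-Hare test
#'
#' Rank-based analogue of the balanced 2x2 ANOVA: all observations are
#' ranked jointly (mid-ranks for ties), factorial sums of squares are
#' computed on the ranks, and each effect's statistic
#' `H = SS_effect / MS_total` -- with `MS_total = SS_total/(N-1)` taken from
#' the actual, possibly tied, ranks -- is referred to a chi-square with 1
#' degree of freedom.
#'
#' @param cells list of four numeric samples in the order A1B1, A1B2, A2B1,
#'   A2B2, all the same size.
#' @param alpha significance level.
#' @return list of three `"cfe_test"` records named `A`, `B`, `AB`.
#' @export
srh_test <- function(cells, alpha = 0.05) {
  n <- lengths(cells)
  if (length(cells) != 4 || length(unique(n)) != 1)
    stop("need four balanced cells (A1B1, A1B2, A2B1, A2B2)", call. = FALSE)
  r <- rank(unlist(cells, use.names = FALSE))
  rcells <- split(r, rep(1:4, each = n[1]))
  d <- ss_2x2(rcells)
  ms_total <- sum((r - mean(r))^2) / (d$N - 1)
  out <- lapply(seq_along(d$ss), function(i) {
    if (ms_total == 0) return(new_test_outcome(0, 1, 1, alpha, "srh"))
    H <- d$ss[i] / ms_total
    new_test_outcome(H, 1, stats::pchisq(H, 1, lower.tail = FALSE), alpha,
                     "srh")
  })
  names(out) <- names(d$ss)
  out
}
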