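## Two-sample members of the test battery.  All return small uniform result
## records so the harness can aggregate them mechanically.  Degenerate
## samples (zero variance everywhere) follow documented rules instead of
## erroring: under severe floor effects whole groups routinely collapse onto
## the boundary value.

new_test_outcome <- function(statistic, df, p_value, alpha, method) {
  statistic <- unname(statistic)
  p_value <- min(max(unname(p_value), 0), 1)
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 reject = is.finite(p_value) && p_value < alpha,
                 alpha = alpha, method = method),
            class = "cfe_test")
}

#' @export
print.cfe_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (%s at alpha = %g)\n",
              x$method, x$statistic, paste(format(x$df, digits = 4),
                                           collapse = ", "),
              x$p_value, if (x$reject) "reject" else "retain", x$alpha))
  invisible(x)
}

## Welch standard error and Satterthwaite df for a mean difference.
welch_se <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  df <- if (se2 > 0)
    se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  else NA_real_
  list(diff = mean(x) - mean(y), se = sqrt(se2), df = df,
       vx = vx, vy = vy, nx = nx, ny = ny)
}

#' Welch's two-sample t-test
#'
#' Two-sided t-test for unequal variances with Satterthwaite degrees of
#' freedom.  When both groups have zero variance the statistic is 0 with
#' p = 1 if the means agree, and infinite with p = 0 otherwise.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param alpha significance level for the `reject` flag.
#' @return a `"cfe_test"` record with `statistic`, `df`, `p_value`, `reject`.
#' @examples
#' welch_t(1:5, 2:6)
#' @export
welch_t <- function(x, y, alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  w <- welch_se(x, y)
  if (w$se == 0) {
    if (w$diff == 0)
      return(new_test_outcome(0, NA_real_, 1, alpha, "welch_t"))
    return(new_test_outcome(sign(w$diff) * Inf, NA_real_, 0, alpha, "welch_t"))
  }
  stat <- w$diff / w$se
  p <- 2 * stats::pt(-abs(stat), w$df)
  new_test_outcome(stat, w$df, p, alpha, "welch_t")
}

#' Yuen's trimmed-means t-test
#'
#' Compares gamma-trimmed means using Winsorized variances and Yuen's
#' degrees of freedom.  With `gamma = 0` it reproduces [welch_t()] exactly.
#'
#' @param x,y numeric samples.
#' @param gamma trim proportion in `[0, 0.5)`; the `floor(gamma * n)`
#'   smallest and largest values of each group are discarded.
#' @param alpha significance level.
#' @return a `"cfe_test"` record.
#' @export
yuen_trimmed_t <- function(x, y, gamma = 0.2, alpha = 0.05) {
  if (gamma < 0 || gamma >= 0.5)
    stop("'gamma' must lie in [0, 0.5)", call. = FALSE)
  yuen_part <- function(v) {
    n <- length(v)
    g <- floor(gamma * n)
    h <- n - 2 * g
    if (h < 2) stop("over-trimming: fewer than 2 values remain", call. = FALSE)
    sv <- sort(v)
    tmean <- mean(sv[(g + 1):(n - g)])
    w <- pmin(pmax(v, sv[g + 1]), sv[n - g])       # Winsorized sample
    swv <- stats::var(w)
    list(tmean = tmean, d = swv * (n - 1) / (h * (h - 1)), h = h)
  }
  a <- yuen_part(x); b <- yuen_part(y)
  se2 <- a$d + b$d
  diff <- a$tmean - b$tmean
  if (se2 == 0) {
    if (diff == 0)
      return(new_test_outcome(0, NA_real_, 1, alpha, "yuen_t"))
    return(new_test_outcome(sign(diff) * Inf, NA_real_, 0, alpha, "yuen_t"))
  }
  stat <- diff / sqrt(se2)
  df <- se2^2 / (a$d^2 / (a$h - 1) + b$d^2 / (b$h - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  new_test_outcome(stat, df, p, alpha, "yuen_t")
}

#' Mann-Whitney rank-sum test
#'
#' Normal approximation with mid-ranks, tie-corrected variance and
#' continuity correction (the data downstream of a floor effect are heavily
#' tied, so the tie correction is essential).  All values identical gives
#' p = 1.
#'
#' @param x,y numeric samples.
#' @param alpha significance level.
#' @return a `"cfe_test"` record whose `statistic` is the U statistic of the
#'   first sample.
#' @export
mann_whitney <- function(x, y, alpha = 0.05) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  tie_tab <- tabulate(match(r, unique(r)))
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(new_test_outcome(U, NA_real_, 1, alpha, "mann_whitney"))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  new_test_outcome(U, NA_real_, p, alpha, "mann_whitney")
}

#' Normal-based confidence interval for the mean group difference
#'
#' `diff +/- z * SE` with the Welch standard error, the interval procedure
#' used alongside the Welch test throughout the harness.
#'
#' @param x,y numeric samples.
#' @param level confidence level.
#' @return list (`"cfe_interval"`) with `point`, `lower`, `upper`, `level`,
#'   `se`.
#' @export
mean_diff_ci <- function(x, y, level = 0.95) {
  w <- welch_se(x, y)
  z <- stats::qnorm((1 + level) / 2)
  structure(list(point = w$diff, lower = w$diff - z * w$se,
                 upper = w$diff + z * w$se, level = level, se = w$se),
            class = "cfe_interval")
}

#' Cohen's d with a normal-approximation confidence interval
#'
#' For equal group sizes `n`: `d = (mean(x) - mean(y)) / sqrt((v0 + v1)/2)`
#' and `SE_d = sqrt(2/n + d^2/(4n))`.  Both variances zero leaves `d`
#' undefined (`NA` point with `defined = FALSE`).
#'
#' @param x,y numeric samples of equal length.
#' @param level confidence level.
#' @return list (`"cfe_interval"`) with `point`, `lower`, `upper`, `level`,
#'   `se`, `defined`.
#' @export
cohens_d_ci <- function(x, y, level = 0.95) {
  n <- length(x)
  if (length(y) != n)
    stop("cohens_d_ci assumes equal group sizes", call. = FALSE)
  v0 <- stats::var(x); v1 <- stats::var(y)
  pooled <- sqrt((v0 + v1) / 2)
  if (pooled == 0)
    return(structure(list(point = NA_real_, lower = NA_real_,
                          upper = NA_real_, level = level, se = NA_real_,
                          defined = FALSE), class = "cfe_interval"))
  d <- (mean(x) - mean(y)) / pooled
  se <- sqrt(2 / n + d^2 / (4 * n))
  z <- stats::qnorm((1 + level) / 2)
  structure(list(point = d, lower = d - z * se, upper = d + z * se,
                 level = level, se = se, defined = TRUE),
            class = "cfe_interval")
}

#' TOST equivalence test
#'
#' Two one-sided Welch tests of `diff <= -threshold` and
#' `diff >= threshold`; the groups are declared equivalent when both reject
#' at `alpha`.
#'
#' @param x,y numeric samples.
#' @param threshold positive equivalence margin on the mean-difference scale.
#' @param alpha level of each one-sided test.
#' @return list (`"cfe_equivalence"`) with `threshold`, `equivalent`,
#'   `p_lower`, `p_upper`.
#' @export
tost <- function(x, y, threshold, alpha = 0.05) {
  if (threshold <= 0) stop("'threshold' must be > 0", call. = FALSE)
  w <- welch_se(x, y)
  if (w$se == 0) {
    eq <- abs(w$diff) < threshold
    p <- as.numeric(!eq)  # 0/1 limiting p-values
    return(structure(list(threshold = threshold, equivalent = eq,
                          p_lower = p, p_upper = p),
                     class = "cfe_equivalence"))
  }
  t_lower <- (w$diff + threshold) / w$se   # H0: diff <= -threshold
  t_upper <- (w$diff - threshold) / w$se   # H0: diff >= +threshold
  p_lower <- stats::pt(t_lower, w$df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, w$df)
  structure(list(threshold = threshold,
                 equivalent = p_lower < alpha && p_upper < alpha,
                 p_lower = p_lower, p_upper = p_upper),
            class = "cfe_equivalence")
}
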