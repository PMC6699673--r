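#' Invert the digamma function
#'
#' Solves `digamma(x) = y` for `x > 0` by Newton iteration with the trigamma
#' derivative.  The initial guess uses the approximation
#' `digamma(x) ~ log(x - 0.5)`, i.e. `x0 = exp(y) + 0.5`, which is accurate
#' for moderate `y` and safely on the correct branch for very negative `y`.
#'
#' @param y numeric vector of digamma values (finite).
#' @param tol convergence tolerance on `|digamma(x) - y|`.
#' @param max_iter maximum Newton iterations.
#' @return `x` with `digamma(x) = y` to within `tol`; strictly increasing
#'   in `y`.
#' @examples
#' digamma_inverse(digamma(3.7))
#' @export
digamma_inverse <- function(y, tol = 1e-12, max_iter = 100L) {
  if (any(!is.finite(y))) stop("'y' must be finite", call. = FALSE)
  x <- exp(y) + 0.5
  for (i in seq_len(max_iter)) {
    f <- digamma(x) - y
    if (all(abs(f) < tol)) return(x)
    step <- f / trigamma(x)
    xn <- x - step
    ## step-halving keeps the iterate on (0, Inf)
    bad <- xn <= 0
    while (any(bad)) {
      step[bad] <- step[bad] / 2
      xn <- x - step
      bad <- xn <= 0
    }
    x <- xn
  }
  f <- digamma(x) - y
  if (any(abs(f) >= 1e-10))
    stop(sprintf("digamma_inverse failed to converge (last iterate %g, residual %g)",
                 x[which.max(abs(f))], max(abs(f))), call. = FALSE)
  x
}

#' Natural (family-native) parameters from CFE constraints
#'
#' Inverts the expectation constraints of a [cfe_params()] object into the
#' family's native parametrization: shape pairs for beta/beta-prime/
#' beta-binomial, gamma shape for the generalized gamma, inverse-Gaussian
#' mean/shape for the Wald, and pass-through location/scale/thresholds for
#' the ordered logistic model.
#'
#' @param params a [cfe_params()] object.
#' @return a list of class `"cfe_natural"` whose fields depend on the family.
#' @export
natural_params <- function(params) {
  stopifnot(inherits(params, "cfe_params"))
  np <- switch(params$family,
    gengamma = solve_gengamma_shape(params$c_l, params$c_n, params$b_scale),
    wald = list(mean = 1 / params$c_l, ig_shape = 1 / params$s_diff^2,
                drift = params$c_l, s_diff = params$s_diff),
    betaprime = solve_betaprime(params$c_l, params$c_n),
    beta = solve_beta(params$c_l, params$c_u),
    betabinomial = c(solve_beta(params$c_l, params$c_u),
                     list(size = params$n_levels)),
    olrm = list(location = params$c_l, scale = params$c_v,
                thresholds = params$thresholds))
  structure(c(list(family = params$family), np), class = "cfe_natural")
}

#' Solve the beta digamma system
#'
#' Finds the standard beta shapes `(alpha, beta)` satisfying
#' `E[log Y] = psi(alpha) - psi(alpha + beta) = c_l` and
#' `E[log(1 - Y)] = psi(beta) - psi(alpha + beta) = c_u` by 2-D Newton
#' iteration with the trigamma Jacobian.  The initial guess solves the same
#' system under the approximation `psi(x) ~ log(x - 0.5)`, which is available
#' in closed form.
#'
#' @param c_l,c_u constraint values; must satisfy `c_l < 0`, `c_u < 0` and
#'   `exp(c_l) + exp(c_u) < 1`.
#' @param tol residual tolerance.
#' @param max_iter maximum Newton iterations.
#' @return list with `alpha`, `beta_shape` (both positive).
#' @examples
#' solve_beta(-1, -1)  # the uniform distribution: alpha = beta = 1
#' @export
solve_beta <- function(c_l, c_u, tol = 1e-11, max_iter = 200L) {
  c_l <- unname(c_l); c_u <- unname(c_u)
  check_beta_feasible(c_l, c_u)
  u <- exp(c_l); v <- exp(c_u)
  ## log(x - 0.5) approximation gives alpha - 0.5 = u*T, beta - 0.5 = v*T
  ## with T = alpha + beta - 0.5, hence T = 0.5 / (1 - u - v).
  Tg <- 0.5 / (1 - u - v)
  ab <- c(0.5 + u * Tg, 0.5 + v * Tg)
  resid <- function(ab) {
    d <- digamma(ab[1] + ab[2])
    c(digamma(ab[1]) - d - c_l, digamma(ab[2]) - d - c_u)
  }
  r <- resid(ab)
  for (i in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    t12 <- trigamma(ab[1] + ab[2])
    J <- matrix(c(trigamma(ab[1]) - t12, -t12,
                  -t12, trigamma(ab[2]) - t12), 2, 2)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step))
      stop("solve_beta: singular Jacobian", call. = FALSE)
    ab_new <- ab - step
    ## halve the step on overshoot into non-positive shapes or residual growth
    for (h in 1:60) {
      if (all(ab_new > 0) && max(abs(resid(ab_new))) <= max(abs(r))) break
      step <- step / 2
      ab_new <- ab - step
    }
    ab <- ab_new
    r <- resid(ab)
  }
  if (max(abs(r)) >= 1e-8) {
    worst <- if (abs(r[1]) >= abs(r[2])) "c_l (E[log Y])" else "c_u (E[log(1-Y)])"
    stop(sprintf("solve_beta did not converge; offending constraint %s, residual %g",
                 worst, max(abs(r))), call. = FALSE)
  }
  list(alpha = ab[1], beta_shape = ab[2])
}

#' Solve the generalized-gamma shape from its floor constraint
#'
#' The generalized gamma satisfies `c_l = log b + psi(a) / c_n`; given the
#' power `c_n` and scale `b` the shape is
#' `a = digamma_inverse(c_n * (c_l - log b))`.
#'
#' @param c_l floor constraint `E[log Y]`.
#' @param c_n positive power parameter.
#' @param b_scale positive scale parameter.
#' @return list with `shape`, plus the pass-through `power` and `scale`.
#' @export
solve_gengamma_shape <- function(c_l, c_n, b_scale = 1) {
  stopifnot(is.finite(c_l), c_n > 0, b_scale > 0)
  a <- unname(digamma_inverse(c_n * (c_l - log(b_scale))))
  list(shape = a, power = unname(c_n), scale = unname(b_scale))
}

#' Solve the beta-prime digamma system
#'
#' Finds shapes `(a, b)` with `E[log Y] = psi(a) - psi(b) = c_l` and
#' `E[log(1 + Y)] = psi(a + b) - psi(b) = c_log1p`.  The first equation is
#' solved exactly for `a` given `b` via [digamma_inverse()]; the remaining
#' scalar equation in `b` is bracketed and solved on the log scale, and the
#' pair is polished by a 2-D Newton step to the target residual.
#'
#' The system is feasible iff `c_log1p > log(1 + exp(c_l))` (the limit of
#' `psi(a+b) - psi(b)` as `b` grows with the first constraint held).
#'
#' @param c_l floor constraint `E[log Y]`.
#' @param c_log1p second constraint `E[log(1 + Y)]`, positive.
#' @param tol residual tolerance.
#' @return list with `alpha`, `beta_shape`.
#' @export
solve_betaprime <- function(c_l, c_log1p, tol = 1e-11) {
  c_l <- unname(c_l); c_log1p <- unname(c_log1p)
  if (!is.finite(c_l)) stop("'c_l' must be finite", call. = FALSE)
  if (!is.finite(c_log1p) || c_log1p <= 0)
    stop("'c_log1p' must be > 0", call. = FALSE)
  if (c_log1p <= log1p(exp(c_l)))
    stop("betaprime constraints infeasible: require c_log1p > log(1 + exp(c_l))",
         call. = FALSE)
  a_of_b <- function(b) digamma_inverse(c_l + digamma(b))
  h <- function(lb) {
    b <- exp(lb)
    a <- a_of_b(b)
    digamma(a + b) - digamma(b) - c_log1p
  }
  ## h decreases from +Inf (b -> 0) to log(1+exp(c_l)) - c_log1p < 0 (b -> Inf)
  lo <- 0; hi <- 0
  while (h(lo) < 0 && lo > -700) lo <- lo - 2
  while (h(hi) > 0 && hi < 700) hi <- hi + 2
  if (h(lo) < 0 || h(hi) > 0)
    stop("solve_betaprime: failed to bracket the root", call. = FALSE)
  lb <- stats::uniroot(h, c(lo, hi), tol = 1e-12)$root
  b <- exp(lb)
  a <- a_of_b(b)
  ## Newton polish on (a, b) with the digamma-system Jacobian
  resid <- function(ab) c(digamma(ab[1]) - digamma(ab[2]) - c_l,
                          digamma(ab[1] + ab[2]) - digamma(ab[2]) - c_log1p)
  ab <- c(a, b)
  r <- resid(ab)
  for (i in 1:50) {
    if (max(abs(r)) < tol) break
    tab <- trigamma(ab[1] + ab[2])
    J <- matrix(c(trigamma(ab[1]), -trigamma(ab[2]),
                  tab, tab - trigamma(ab[2])), 2, 2, byrow = TRUE)
    step <- solve(J, r)
    ab_new <- ab - step
    for (hh in 1:60) {
      if (all(ab_new > 0) && max(abs(resid(ab_new))) <= max(abs(r))) break
      step <- step / 2
      ab_new <- ab - step
    }
    ab <- ab_new
    r <- resid(ab)
  }
  if (max(abs(r)) >= 1e-8)
    stop(sprintf("solve_betaprime did not converge (residual %g)", max(abs(r))),
         call. = FALSE)
  list(alpha = ab[1], beta_shape = ab[2])
}
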