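#' CFE-parametrized distribution families
#'
#' `cfe_params()` bundles a distribution family tag with the constraint
#' parameters that control the severity of its ceiling/floor effect (CFE) and
#' with any family-specific nuisance parameters.  The constraints are
#' expectations of the maximum-entropy functionals: `c_l = E[log Y]` on the
#' floor side and, for doubly bounded families, `c_u = E[log(1 - Y)]` on the
#' ceiling side (for the beta-binomial these act on the latent beta success
#' probability).  More negative values mean a more severe boundary effect.
#'
#' Family-specific slots:
#' \describe{
#'   \item{gengamma}{`c_l`, power `c_n > 0`, scale `b_scale > 0`.  Density of
#'     `Y = b G^(1/c_n)` with `G ~ Gamma(a)`; `c_l = log b + psi(a)/c_n`.}
#'   \item{wald}{first-passage time of drifted Brownian motion with boundary
#'     separation fixed at 1.  The `c_l` slot carries the drift `b > 0`
#'     (severity increases with `b`; the sweep axis is reversed when
#'     reported), `s_diff > 0` is the diffusion rate.  Equivalent to an
#'     inverse-Gaussian with mean `1/b` and shape `1/s_diff^2`.}
#'   \item{betaprime}{`c_l = E[log Y] = psi(a) - psi(b)` plus second
#'     constraint `c_n = E[log(1 + Y)] = psi(a+b) - psi(b) > 0`.}
#'   \item{beta}{`c_l = E[log Y]`, `c_u = E[log(1-Y)]`, both `< 0` with
#'     `exp(c_l) + exp(c_u) < 1` (Jensen feasibility).}
#'   \item{betabinomial}{beta constraints on the latent success probability
#'     plus trial count `n_levels` (outcomes `0..n_levels`).}
#'   \item{olrm}{ordered logistic regression: latent
#'     `Z ~ Logistic(c_l, c_v)` cut at strictly increasing `thresholds`
#'     (length `n_levels - 1`); the outcome is the number of thresholds below
#'     `Z`.  Negative `c_l` pushes mass onto the floor category.}
#' }
#'
#' @param family one of `"gengamma"`, `"wald"`, `"betaprime"`, `"beta"`,
#'   `"betabinomial"`, `"olrm"`.
#' @param c_l floor-effect constraint (drift `b` for `wald`, latent location
#'   for `olrm`).
#' @param c_u ceiling-effect constraint (`beta`, `betabinomial` only).
#' @param c_n power parameter (`gengamma`) or the `E[log(1+Y)]` constraint
#'   (`betaprime`).
#' @param b_scale scale parameter `b` of the generalized gamma (default 1).
#' @param s_diff diffusion rate `s` of the Wald process.
#' @param n_levels beta-binomial trial count, or number of ordered categories
#'   for `olrm` (derived from `thresholds` when omitted).
#' @param thresholds strictly increasing cutpoints for `olrm`.
#' @param c_v logistic scale for `olrm`.
#' @return an object of class `"cfe_params"`.
#' @examples
#' cfe_params("gengamma", c_l = -1, c_n = 1)
#' cfe_params("beta", c_l = -3, c_u = -0.2)
#' @export
cfe_params <- function(family = c("gengamma", "wald", "betaprime", "beta",
                                  "betabinomial", "olrm"),
                       c_l = NULL, c_u = NULL, c_n = NULL, b_scale = 1,
                       s_diff = NULL, n_levels = NULL, thresholds = NULL,
                       c_v = NULL) {
  family <- match.arg(family)
  chk_num <- function(x, nm, positive = FALSE) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number for family '%s'",
                   nm, family), call. = FALSE)
    if (positive && x <= 0)
      stop(sprintf("'%s' must be > 0 for family '%s'", nm, family),
           call. = FALSE)
    x
  }
  p <- list(family = family)
  switch(family,
    gengamma = {
      p$c_l <- chk_num(c_l, "c_l")
      p$c_n <- chk_num(c_n, "c_n", positive = TRUE)
      p$b_scale <- chk_num(b_scale, "b_scale", positive = TRUE)
    },
    wald = {
      p$c_l <- chk_num(c_l, "c_l (drift b)", positive = TRUE)
      p$s_diff <- chk_num(s_diff, "s_diff", positive = TRUE)
    },
    betaprime = {
      p$c_l <- chk_num(c_l, "c_l")
      p$c_n <- chk_num(c_n, "c_n", positive = TRUE)
      if (p$c_n <= log1p(exp(p$c_l)))
        stop("betaprime constraints infeasible: require c_n > log(1 + exp(c_l))",
             call. = FALSE)
    },
    beta = ,
    betabinomial = {
      p$c_l <- chk_num(c_l, "c_l")
      p$c_u <- chk_num(c_u, "c_u")
      check_beta_feasible(p$c_l, p$c_u)
      if (family == "betabinomial") {
        n <- chk_num(n_levels, "n_levels", positive = TRUE)
        if (n != round(n)) stop("'n_levels' must be an integer", call. = FALSE)
        p$n_levels <- as.integer(n)
      }
    },
    olrm = {
      p$c_l <- chk_num(c_l, "c_l")
      p$c_v <- chk_num(c_v, "c_v", positive = TRUE)
      if (is.null(thresholds) || length(thresholds) < 1L ||
          any(!is.finite(thresholds)))
        stop("'thresholds' must be a finite numeric vector for 'olrm'",
             call. = FALSE)
      if (any(diff(thresholds) <= 0))
        stop("'thresholds' must be strictly increasing", call. = FALSE)
      p$thresholds <- as.numeric(thresholds)
      p$n_levels <- length(thresholds) + 1L
      if (!is.null(n_levels) && n_levels != p$n_levels)
        stop("'n_levels' must equal length(thresholds) + 1", call. = FALSE)
    })
  structure(p, class = "cfe_params")
}

## Jensen feasibility for the beta two-constraint system: E[log Q] < log E[Q]
## and E[log(1-Q)] < log(1 - E[Q]) force exp(c_l) + exp(c_u) < 1.
check_beta_feasible <- function(c_l, c_u) {
  if (c_l >= 0 || c_u >= 0)
    stop("beta constraints require c_l < 0 and c_u < 0", call. = FALSE)
  if (exp(c_l) + exp(c_u) >= 1)
    stop("beta constraints infeasible: exp(c_l) + exp(c_u) must be < 1",
         call. = FALSE)
  invisible(TRUE)
}

#' Test feasibility of CFE constraints without throwing
#'
#' @param family family tag as in [cfe_params()].
#' @param c_l,c_u,c_n constraint values to probe.
#' @return `TRUE` if the constraints admit a distribution, else `FALSE`.
#' @export
cfe_feasible <- function(family, c_l, c_u = NULL, c_n = NULL) {
  switch(family,
    beta = ,
    betabinomial = is.finite(c_l) && is.finite(c_u) && c_l < 0 && c_u < 0 &&
      exp(c_l) + exp(c_u) < 1,
    betaprime = is.finite(c_l) && !is.null(c_n) && c_n > log1p(exp(c_l)),
    wald = is.finite(c_l) && c_l > 0,
    is.finite(c_l))
}

#' @export
print.cfe_params <- function(x, ...) {
  cat("CFE parameters -- family:", x$family, "\n")
  for (nm in setdiff(names(x), "family"))
    cat(sprintf("  %-10s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

## Offset the severity axis of a template: adds `delta` to the c_l slot
## (for wald this shifts the drift; for olrm the latent location).
offset_c_l <- function(params, delta) {
  if (delta == 0) return(params)
  p <- unclass(params)
  p$c_l <- p$c_l + delta
  ## revalidate cheaply
  do.call(cfe_params, p)
}
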