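## Quadrature oracles for the constraint functionals, independent of the
## Newton solvers they check.

# E[log Y] and E[log(1-Y)] under Beta(a, b); the second moment reuses the
# first under the reflection Y -> 1 - Y to keep the integrand singularity
# at the origin, where integrate() handles it well.
beta_constraints_quadrature <- function(a, b) {
  elog <- function(a, b)
    stats::integrate(function(y) log(y) * stats::dbeta(y, a, b), 0, 1,
                     rel.tol = 1e-12)$value
  c(c_l = elog(a, b), c_u = elog(b, a))
}

# E[log Y] and E[log(1+Y)] under BetaPrime(a, b), via the representation
# Y = Q/(1-Q) with Q ~ Beta(a, b): log Y = log Q - log(1-Q) and
# log(1+Y) = -log(1-Q), so both reduce to beta-moment quadrature.
betaprime_constraints_quadrature <- function(a, b) {
  q <- beta_constraints_quadrature(a, b)
  c(c_l = unname(q["c_l"] - q["c_u"]), c_log1p = unname(-q["c_u"]))
}

# Mann-Whitney U of sample x vs y by direct pair counting.
u_stat_bruteforce <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# JZS numerator by Riemann sum on the substitution g = u/(1-u).
jzs_bf10_riemann <- function(t, nx, ny, prior_scale = 1, n_grid = 2e5) {
  nu <- nx + ny - 2
  Neff <- nx * ny / (nx + ny) * prior_scale^2
  u <- (seq_len(n_grid) - 0.5) / n_grid
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  f <- (1 + Neff * g)^-0.5 *
    (1 + t^2 / ((1 + Neff * g) * nu))^(-(nu + 1) / 2) *
    (2 * pi)^-0.5 * g^-1.5 * exp(-1 / (2 * g))
  num <- sum(f * jac) / n_grid
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}
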