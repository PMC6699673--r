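# cfesim

Monte-Carlo study of how **ceiling and floor effects** (CFE) degrade
statistical inference — for methodologists, psychometricians and
biostatisticians who need to know *which* test survives a bounded,
bunched-up measure, and by how much.

A measure with a floor does not merely censor: the whole distribution
deforms as the latent quantity approaches the bound — the mean saturates,
the variance collapses, the skew diverges.  `cfesim` makes that severity a
single swept parameter.  Each generating family is parametrized by the
expectation of its boundary functional, `c_l = E[log Y]` on the floor side
and `c_u = E[log(1 − Y)]` at a ceiling (the log geometric means), which
maximum-entropy arguments connect to familiar distributions:

* beta: `c_l = ψ(α) − ψ(α+β)`, `c_u = ψ(β) − ψ(α+β)`
* generalized gamma: `c_l = log b + ψ(a)/c_n`
* beta prime: `c_l = ψ(a) − ψ(b)`, `E[log(1+Y)] = ψ(a+b) − ψ(b)`
* beta-binomial (constraints on the latent success probability),
* Wald/inverse-Gaussian (drift = severity), and an ordered logistic model
  for rating scales.

The digamma systems are inverted by Newton iteration
(`digamma_inverse()`, `solve_beta()`, `solve_betaprime()`, ...), two
groups are placed at `c_l0` and `c_l0 + Δ`, and a battery of tests is
scored over thousands of replications while `c_l0` sweeps toward the
boundary: Welch and Yuen (trimmed) t-tests, Mann–Whitney, Kruskal–Wallis,
one-way and balanced 2×2 ANOVA, the Scheirer–Ray–Hare rank test, a JZS
Bayes-factor t-test, TOST equivalence with simulation-calibrated margins,
and normal-based intervals for the mean difference and Cohen's *d* — each
parametric method also applied to log- or logit-transformed data.

## Worked example

Two groups of 50 from the generalized gamma family (`c_n = 1`, effect
`Δ = 0.25` on the log-geometric-mean scale), sweeping the floor severity
`c_l0` over five points of `[-4, 4]`, 2000 replications per cell:

```r
library(cfesim)
tab <- sweep_grid("gengamma", "two_group", c_l0_points = 5,
                  c_l_delta_values = 0.25, reps = 2000, seed = 1,
                  methods = c("welch_raw", "welch_trans", "mw"))
tab[, c("c_l0", "reject_welch_raw", "reject_welch_trans", "reject_mw")]
#>   c_l0 reject_welch_raw reject_welch_trans reject_mw
#> 1   -4           0.0380             0.0620    0.0595
#> 2   -2           0.0635             0.0910    0.0845
#> 3    0           0.2025             0.2765    0.2430
#> 4    2           0.9405             0.9470    0.9310
#> 5    4           1.0000             1.0000    1.0000
max_gap(tab, "reject_welch_trans", "reject_welch_raw")
#> [1] 7.4
```

Read: all three tests detect the fixed group difference essentially always
when the floor is weak (`c_l0 = 4`), and all of them degrade as the floor
severity grows (leftward) — the bunching destroys the information itself.
But they do not degrade equally: through the transition the *t*-test on
log data stays ahead of the raw-data *t*-test, by up to 7.4 percentage
points on this coarse grid, and the Mann–Whitney test tracks the log-*t*
closely because its rank statistic is invariant to the transform.

Other entry points: `run_scenario()` (a single cell, with TOST/Bayes/
interval summaries), `calibrate_tost_threshold()`, `cfe_condition_report()`
(audits the four formal CFE limit conditions on the moment curves),
`recovery_sweep()` (maximum-likelihood recovery of a group difference from
ordinal data under a ceiling, ordered-logit vs beta-binomial likelihoods),
`run_selftest()` (exact-null calibration of the whole battery), and
`cfe_sample()` / `cfe_moments()` for the families themselves.

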