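test_that("constellation coefficient vectors carry the stated contrasts", {
  # interaction contrast d11 - d12 - d21 + d22
  ic <- function(d) d[1] - d[2] - d[3] + d[4]
  me <- function(d) c(sum(d[1:2]) - sum(d[3:4]), sum(d[c(1, 3)]) - sum(d[c(2, 4)]))
  expect_equal(ic(constellation_d("no_X")), 0)
  expect_true(all(me(constellation_d("no_X")) != 0))
  expect_equal(me(constellation_d("no_ME")), c(0, 0))
  expect_true(ic(constellation_d("no_ME")) != 0)
  # the three interaction constellations are permutations of one multiset
  ms <- sort(constellation_d("uncrossed"))
  expect_equal(sort(constellation_d("crossed")), ms)
  expect_equal(sort(constellation_d("double_crossed")), ms)
})

test_that("scenario group sizes follow the two/three/four-group design", {
  expect_equal(scenario_config("gengamma", "two_group", 0, 0.25)$group_size, 50L)
  expect_equal(scenario_config("gengamma", "three_group", 0, 0.25)$group_size, 33L)
  expect_equal(scenario_config("gengamma", "factorial_2x2", 0, 0.25)$group_size, 25L)
})

test_that("sweeps are bit-reproducible under the same master seed", {
  a <- sweep_grid("gengamma", "two_group", c_l0_points = 3,
                  c_l_delta_values = 0.25, reps = 50, seed = 7,
                  methods = c("welch_raw", "mw"))
  b <- sweep_grid("gengamma", "two_group", c_l0_points = 3,
                  c_l_delta_values = 0.25, reps = 50, seed = 7,
                  methods = c("welch_raw", "mw"))
  expect_identical(a, b)
})

test_that("infeasible beta cells are flagged and never sampled", {
  tab <- sweep_grid("beta", "two_group", c_l0_points = 25,
                    c_l_delta_values = 3, reps = 10, seed = 8,
                    methods = "welch_raw")
  # group B needs exp(c_l0 + 3) + exp(-0.2) < 1, i.e. c_l0 < -4.707
  expect_true(all(tab$infeasible[tab$c_l0 > -4.7]))
  expect_true(all(!tab$infeasible[tab$c_l0 < -4.8]))
  expect_true(all(is.na(tab$reject_welch_raw[tab$infeasible])))
  expect_true(all(!is.na(tab$reject_welch_raw[!tab$infeasible])))
})

test_that("the sweep grid covers the documented reference ranges", {
  expect_equal(family_defaults("gengamma")$c_l_range, c(-4, 4))
  expect_equal(family_defaults("betaprime")$np_value, 0.155)
  expect_equal(family_defaults("betabinomial")$c_l_delta, 4)
  tab <- sweep_grid("gengamma", "two_group", c_l0_points = 5,
                    c_l_delta_values = c(0.25, 0.5), np_values = c(1, 2),
                    reps = 5, seed = 9, methods = "welch_raw")
  expect_equal(nrow(tab), 5 * 2 * 2)
  expect_equal(range(tab$c_l0), c(-4, 4))
})

test_that("max_gap basics: zero against itself, permutation invariance", {
  tab <- sweep_grid("gengamma", "two_group", c_l0_points = 4,
                    c_l_delta_values = 0.25, reps = 30, seed = 10,
                    methods = c("welch_raw", "welch_trans"))
  expect_equal(max_gap(tab, "reject_welch_raw", "reject_welch_raw"), 0)
  g1 <- max_gap(tab, "reject_welch_trans", "reject_welch_raw")
  g2 <- max_gap(tab[sample(nrow(tab)), ], "reject_welch_trans",
                "reject_welch_raw")
  expect_equal(g1, g2)
  expect_error(max_gap(tab, "reject_welch_raw", "reject_mw"), "missing")
})

test_that("power is high at weak floor effect for the log-t on gamma data", {
  cfg <- scenario_config("gengamma", "two_group", c_l0 = 2, c_l_delta = 0.25,
                         reps = 600, seed = 12)
  res <- run_scenario(cfg, methods = "welch_trans")
  expect_gt(res$reject_welch_trans, 0.5)
})

test_that("detection degrades monotonically with floor severity (gamma)", {
  tab <- sweep_grid("gengamma", "two_group", c_l0_points = 5,
                    c_l_delta_values = 0.25, reps = 800, seed = 13,
                    methods = "welch_trans")
  r <- tab$reject_welch_trans[order(tab$c_l0)]  # severity decreases with c_l0
  expect_true(all(diff(r) > -0.08))  # non-decreasing up to Monte-Carlo noise
})

test_that("raw Welch-t stays in [0, 0.1] across the beta-prime sweep", {
  tab <- sweep_grid("betaprime", "two_group", c_l0_points = 7,
                    c_l_delta_values = 2, reps = 500, seed = 14,
                    methods = "welch_raw")
  ok <- !tab$infeasible
  expect_true(any(ok))
  expect_true(all(tab$reject_welch_raw[ok] <= 0.1))
})

test_that("run_scenario aggregates interval and Bayesian summaries", {
  thr <- list(raw = 1, trans = 0.25)
  cfg <- scenario_config("gengamma", "two_group", c_l0 = 2, c_l_delta = 0.25,
                         reps = 40, seed = 15, tost_threshold = thr)
  res <- run_scenario(cfg)
  expect_true(all(c("median_ph0_raw", "median_ph0_trans", "equiv_raw",
                    "equiv_trans", "median_diff_point", "median_d_point")
                  %in% names(res)))
  expect_true(res$median_ph0_raw >= 0 && res$median_ph0_raw <= 1)
  expect_true(res$equiv_raw >= 0 && res$equiv_raw <= 1)
})

test_that("factorial scenarios run all three effect tests", {
  cfg <- scenario_config("gengamma", "factorial_2x2", c_l0 = 2,
                         c_l_delta = 0.25, constellation = "crossed",
                         reps = 30, seed = 16)
  res <- run_scenario(cfg)
  expect_true(all(c("reject_anova2_raw_A", "reject_anova2_trans_AB",
                    "reject_srh_B") %in% names(res)))
})

test_that("wald severity runs on the reversed drift axis", {
  # drift 0 is an invalid cell, flagged infeasible rather than sampled
  tab <- sweep_grid("wald", "two_group", c_l0_points = 5,
                    c_l_delta_values = 1, reps = 20, seed = 17,
                    methods = "welch_raw")
  expect_true(tab$infeasible[tab$c_l0 == 0])
  expect_false(any(tab$infeasible[tab$c_l0 > 0]))
})
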