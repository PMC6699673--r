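#' Reference parameter grids for each family
#'
#' The sweep ranges and representative values used by the simulation study:
#' the `c_l` sweep range, the group-difference offset `c_l_delta` (its
#' representative value and its own range), and the family-specific nuisance
#' parameter with its range.  For the Wald family the `c_l` slot carries the
#' drift `b`, whose severity axis runs in the reverse direction (larger
#' drift = stronger floor effect), which is why its range is written high to
#' low.
#'
#' @param family family tag as in [cfe_params()].
#' @return list with `c_l_range`, `c_l_delta`, `c_l_delta_range`,
#'   `np_label`, `np_value`, `np_range`, and a `template` [cfe_params()]
#'   object at the representative values (mid-range `c_l`).
#' @export
family_defaults <- function(family) {
  def <- switch(family,
    gengamma = list(c_l_range = c(-4, 4), c_l_delta = 0.25,
                    c_l_delta_range = c(0, 1), np_label = "c_n",
                    np_value = 1, np_range = c(0, 2)),
    wald = list(c_l_range = c(20, 0), c_l_delta = 1,
                c_l_delta_range = c(0, 4), np_label = "s_diff",
                np_value = 1, np_range = c(0, 2)),
    betaprime = list(c_l_range = c(-10, -2), c_l_delta = 2,
                     c_l_delta_range = c(0, 8), np_label = "c_n",
                     np_value = 0.155, np_range = c(0.155, 0.155)),
    beta = list(c_l_range = c(-20, 0), c_l_delta = 3,
                c_l_delta_range = c(1, 5), np_label = "c_u",
                np_value = -0.2, np_range = c(-0.2, -0.2)),
    betabinomial = list(c_l_range = c(-5, -1), c_l_delta = 4,
                        c_l_delta_range = c(1, 8), np_label = "n_levels",
                        np_value = 7, np_range = c(3, 15)),
    olrm = list(c_l_range = c(-5, 5), c_l_delta = 0.8,
                c_l_delta_range = c(0, 1), np_label = "n_levels",
                np_value = 7, np_range = c(3, 15)),
    stop("unknown family: ", family, call. = FALSE))
  mid <- mean(def$c_l_range)
  def$template <- family_template(family, c_l = mid, np_value = def$np_value)
  def
}

#' Build a family template at given severity and nuisance values
#'
#' @param family family tag.
#' @param c_l severity (floor-constraint) value; drift for `wald`.
#' @param np_value nuisance value (meaning depends on the family, see
#'   [family_defaults()]).
#' @param c_u ceiling constraint for beta (default -0.2, the reference
#'   slice); for betabinomial the reference is -0.3.
#' @param c_v logistic scale for `olrm` (default 0.8).
#' @param thresholds `olrm` cutpoints; defaults to `np_value - 1` equally
#'   spaced thresholds over `[-3, 3]`.
#' @return a [cfe_params()] object.
#' @export
family_template <- function(family, c_l, np_value = family_defaults(family)$np_value,
                            c_u = NULL, c_v = 0.8, thresholds = NULL) {
  switch(family,
    gengamma = cfe_params("gengamma", c_l = c_l, c_n = np_value, b_scale = 1),
    wald = cfe_params("wald", c_l = c_l, s_diff = np_value),
    betaprime = cfe_params("betaprime", c_l = c_l, c_n = np_value),
    beta = cfe_params("beta", c_l = c_l,
                      c_u = if (is.null(c_u)) -0.2 else c_u),
    betabinomial = cfe_params("betabinomial", c_l = c_l,
                              c_u = if (is.null(c_u)) -0.3 else c_u,
                              n_levels = np_value),
    olrm = {
      if (is.null(thresholds))
        thresholds <- seq(-3, 3, length.out = np_value - 1)
      cfe_params("olrm", c_l = c_l, c_v = c_v, thresholds = thresholds)
    },
    stop("unknown family: ", family, call. = FALSE))
}

#' Factorial cell coefficients for the five interaction constellations
#'
#' Cell `c_l` values are `c_l0 + c_l_delta * d` with the coefficient vector
#' `d` over cells (A1B1, A1B2, A2B1, A2B2):
#' \describe{
#'   \item{no_X}{`(0, 1, 2, 3)` -- two additive main effects, zero
#'     interaction contrast.}
#'   \item{no_ME}{`(0, 1, 1, 0)` -- pure interaction, zero main effects.}
#'   \item{uncrossed}{`(0, 1, 2, 5)` -- main effects plus interaction, cell
#'     order preserved within both factors.}
#'   \item{crossed}{`(0, 1, 5, 2)` -- same multiset, order reversed within
#'     one factor.}
#'   \item{double_crossed}{`(0, 2, 5, 1)` -- order reversed within both
#'     factors (disordinal).}
#' }
#' The last three are permutations of one multiset, so they swap the
#' magnitudes of the strong main effect, weak main effect and interaction
#' contrasts while holding the cell values fixed.
#'
#' @param constellation one of the five names above.
#' @return numeric coefficient vector of length 4.
#' @export
constellation_d <- function(constellation = c("no_X", "no_ME", "uncrossed",
                                              "crossed", "double_crossed")) {
  constellation <- match.arg(constellation)
  switch(constellation,
    no_X = c(0, 1, 2, 3),
    no_ME = c(0, 1, 1, 0),
    uncrossed = c(0, 1, 2, 5),
    crossed = c(0, 1, 5, 2),
    double_crossed = c(0, 2, 5, 1))
}

#' Scenario configuration
#'
#' One sweep cell: family template, scenario, severity coordinates and
#' replication settings.  Group sizes follow the study design: 50 per group
#' in the two-group scenario, 33 in the three-group scenario, 25 per cell in
#' the 2x2 factorial.
#'
#' @param family family tag.
#' @param scenario `"two_group"`, `"three_group"` or `"factorial_2x2"`.
#' @param c_l0 base severity value (group A).
#' @param c_l_delta group-difference offset; group B sits at
#'   `c_l0 + c_l_delta`, group C (three-group) at `c_l0 + 2 c_l_delta`, and
#'   factorial cells at `c_l0 + c_l_delta * d`.
#' @param np_value nuisance parameter value (see [family_defaults()]).
#' @param constellation factorial constellation (factorial only).
#' @param reps Monte-Carlo replications (study scale: 10000; a reduced
#'   preset of 2000 is used for desk-scale runs).
#' @param alpha two-sided significance level.
#' @param trim trim proportion for the Yuen test.
#' @param prior_scale JZS Cauchy prior scale.
#' @param tost_threshold equivalence margins: list with elements `raw` and
#'   `trans`, or `NULL` to skip the TOST (thresholds come from
#'   [calibrate_tost_threshold()] and are fixed across the sweep).
#' @param group_size override the scenario's group size.
#' @param seed integer seed for the cell's random stream.
#' @param c_u,c_v,thresholds forwarded to [family_template()].
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(family,
                            scenario = c("two_group", "three_group",
                                         "factorial_2x2"),
                            c_l0, c_l_delta, np_value = NULL,
                            constellation = "no_X", reps = 10000,
                            alpha = 0.05, trim = 0.2, prior_scale = 1,
                            tost_threshold = NULL, group_size = NULL,
                            seed = NULL, c_u = NULL, c_v = 0.8,
                            thresholds = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(np_value)) np_value <- family_defaults(family)$np_value
  if (is.null(group_size))
    group_size <- switch(scenario, two_group = 50L, three_group = 33L,
                         factorial_2x2 = 25L)
  structure(list(family = family, scenario = scenario, c_l0 = c_l0,
                 c_l_delta = c_l_delta, np_value = np_value,
                 constellation = constellation, reps = as.integer(reps),
                 alpha = alpha, trim = trim, prior_scale = prior_scale,
                 tost_threshold = tost_threshold,
                 group_size = as.integer(group_size), seed = seed,
                 c_u = c_u, c_v = c_v, thresholds = thresholds),
            class = "scenario_config")
}

## Offsets (in units of c_l_delta) of the groups/cells of a scenario.
scenario_offsets <- function(config) {
  switch(config$scenario,
    two_group = c(0, 1),
    three_group = c(0, 1, 2),
    factorial_2x2 = constellation_d(config$constellation))
}

## Group parameter objects for a cell, or NULL if any group is infeasible.
scenario_group_params <- function(config) {
  offs <- scenario_offsets(config)
  cl <- config$c_l0 + config$c_l_delta * offs
  ok <- vapply(cl, function(v)
    cfe_feasible(config$family, v,
                 c_u = if (is.null(config$c_u))
                   switch(config$family, beta = -0.2, betabinomial = -0.3, NULL)
                 else config$c_u,
                 c_n = if (config$family == "betaprime") config$np_value else NULL),
    logical(1))
  if (!all(ok)) return(NULL)
  lapply(cl, function(v)
    family_template(config$family, c_l = v, np_value = config$np_value,
                    c_u = config$c_u, c_v = config$c_v,
                    thresholds = config$thresholds))
}

default_methods <- function(scenario) {
  switch(scenario,
    two_group = c("welch_raw", "welch_trans", "yuen", "mw",
                  "jzs_raw", "jzs_trans", "tost_raw", "tost_trans",
                  "diff_ci", "d_ci"),
    three_group = c("anova_raw", "anova_trans", "kw"),
    factorial_2x2 = c("anova2_raw", "anova2_trans", "srh"))
}

#' Run one simulation cell
#'
#' Draws the scenario's groups `reps` times, applies the selected battery
#' members to raw and transformed data, and aggregates rejection
#' proportions (and medians for the interval/Bayesian summaries) into a
#' one-row data frame.
#'
#' Available methods by scenario -- two-group: `welch_raw`, `welch_trans`,
#' `yuen`, `mw`, `jzs_raw`, `jzs_trans`, `tost_raw`, `tost_trans`
#' (require `tost_threshold`), `diff_ci`, `d_ci`; three-group: `anova_raw`,
#' `anova_trans`, `kw`; factorial: `anova2_raw`, `anova2_trans`, `srh`
#' (each reporting main effects `A`, `B` and interaction `AB`).  Rank tests
#' are invariant under the monotone transforms, so they are computed once on
#' the raw data.
#'
#' @param config a [scenario_config()].
#' @param methods character vector of battery members (default: all that
#'   apply to the scenario).
#' @return one-row `data.frame` (a metrics record): grid coordinates, an
#'   `infeasible` flag, `reject_*` proportions, `equiv_*` proportions,
#'   `median_*` summaries and the replication count.
#' @export
run_scenario <- function(config, methods = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(methods)) methods <- default_methods(config$scenario)
  if (!is.null(config$seed)) set.seed(config$seed)
  base <- data.frame(family = config$family, scenario = config$scenario,
                     constellation = if (config$scenario == "factorial_2x2")
                       config$constellation else NA_character_,
                     c_l0 = config$c_l0, c_l_delta = config$c_l_delta,
                     np_value = config$np_value,
                     group_size = config$group_size,
                     reps = config$reps, stringsAsFactors = FALSE)
  gp <- scenario_group_params(config)
  if (is.null(gp)) {
    base$infeasible <- TRUE
    return(base)
  }
  base$infeasible <- FALSE
  tr <- default_transform(config$family)
  nlev <- transform_levels(gp[[1]])
  natives <- lapply(gp, natural_params)
  n <- config$group_size
  alpha <- config$alpha

  needs_tost <- any(c("tost_raw", "tost_trans") %in% methods)
  if (needs_tost && is.null(config$tost_threshold))
    stop("tost methods require 'tost_threshold' (see calibrate_tost_threshold)",
         call. = FALSE)

  acc <- new.env(parent = emptyenv())
  add <- function(key, value) {
    acc[[key]] <- c(acc[[key]], value)
  }

  for (r in seq_len(config$reps)) {
    raw <- lapply(seq_along(gp), function(i)
      cfe_sample(gp[[i]], n, native = natives[[i]]))
    trans <- lapply(raw, function(v) apply_transform(tr, v, n_levels = nlev))
    if (config$scenario == "two_group") {
      x <- raw[[1]]; y <- raw[[2]]; xt <- trans[[1]]; yt <- trans[[2]]
      for (m in methods) {
        switch(m,
          welch_raw = add("reject_welch_raw", welch_t(x, y, alpha)$reject),
          welch_trans = add("reject_welch_trans", welch_t(xt, yt, alpha)$reject),
          yuen = add("reject_yuen",
                     yuen_trimmed_t(x, y, config$trim, alpha)$reject),
          mw = add("reject_mw", mann_whitney(x, y, alpha)$reject),
          jzs_raw = add("ph0_raw",
                        jzs_bayes_ttest(x, y, config$prior_scale)$p_h0),
          jzs_trans = add("ph0_trans",
                          jzs_bayes_ttest(xt, yt, config$prior_scale)$p_h0),
          tost_raw = add("equiv_raw",
                         tost(x, y, config$tost_threshold$raw, alpha)$equivalent),
          tost_trans = add("equiv_trans",
                           tost(xt, yt, config$tost_threshold$trans,
                                alpha)$equivalent),
          diff_ci = {
            ci <- mean_diff_ci(x, y)
            add("diff_point", ci$point); add("diff_lo", ci$lower)
            add("diff_hi", ci$upper)
            cit <- mean_diff_ci(xt, yt)
            add("diff_point_trans", cit$point); add("diff_lo_trans", cit$lower)
            add("diff_hi_trans", cit$upper)
          },
          d_ci = {
            ci <- cohens_d_ci(x, y)
            add("d_point", ci$point); add("d_lo", ci$lower)
            add("d_hi", ci$upper)
          },
          stop("unknown two-group method: ", m, call. = FALSE))
      }
    } else if (config$scenario == "three_group") {
      for (m in methods) {
        switch(m,
          anova_raw = add("reject_anova_raw", anova_oneway(raw, alpha)$reject),
          anova_trans = add("reject_anova_trans",
                            anova_oneway(trans, alpha)$reject),
          kw = add("reject_kw", kruskal_wallis(raw, alpha)$reject),
          stop("unknown three-group method: ", m, call. = FALSE))
      }
    } else {
      for (m in methods) {
        switch(m,
          anova2_raw = {
            f <- anova_2x2(raw, alpha)
            add("reject_anova2_raw_A", f$A$reject)
            add("reject_anova2_raw_B", f$B$reject)
            add("reject_anova2_raw_AB", f$AB$reject)
          },
          anova2_trans = {
            f <- anova_2x2(trans, alpha)
            add("reject_anova2_trans_A", f$A$reject)
            add("reject_anova2_trans_B", f$B$reject)
            add("reject_anova2_trans_AB", f$AB$reject)
          },
          srh = {
            f <- srh_test(raw, alpha)
            add("reject_srh_A", f$A$reject)
            add("reject_srh_B", f$B$reject)
            add("reject_srh_AB", f$AB$reject)
          },
          stop("unknown factorial method: ", m, call. = FALSE))
      }
    }
  }

  keys <- ls(acc)
  for (key in keys) {
    v <- acc[[key]]
    base[[if (grepl("^(reject|equiv)", key)) key else paste0("median_", key)]] <-
      if (grepl("^(reject|equiv)", key)) mean(v) else stats::median(v, na.rm = TRUE)
  }
  base
}

#' Sweep the severity axis (and optionally the full parameter grid)
#'
#' Runs [run_scenario()] over the Cartesian product of `c_l0` points,
#' `c_l_delta` values and nuisance values.  Per-cell seeds are derived from
#' the master seed plus the cell index so every cell is independently
#' reproducible.  Infeasible cells are flagged, never sampled.
#'
#' @param family family tag.
#' @param scenario scenario name.
#' @param c_l0_points number of equally spaced `c_l0` grid points over the
#'   family's sweep range (or a numeric vector of explicit points).
#' @param c_l_delta_values offsets to cross (default: the family's
#'   representative value).
#' @param np_values nuisance values to cross (default: representative).
#' @param reps replications per cell.
#' @param seed master seed.
#' @param methods battery selection forwarded to [run_scenario()].
#' @param constellation factorial constellation.
#' @param c_l_range override the family's sweep range.
#' @param ... forwarded to [scenario_config()] (e.g. `c_u`, `trim`,
#'   `tost_threshold`).
#' @return `data.frame` with one metrics row per cell.
#' @export
sweep_grid <- function(family, scenario = "two_group", c_l0_points = 25,
                       c_l_delta_values = NULL, np_values = NULL,
                       reps = 10000, seed = 1, methods = NULL,
                       constellation = "no_X", c_l_range = NULL, ...) {
  def <- family_defaults(family)
  if (is.null(c_l_range)) c_l_range <- def$c_l_range
  grid_cl0 <- if (length(c_l0_points) == 1)
    seq(c_l_range[1], c_l_range[2], length.out = c_l0_points)
  else as.numeric(c_l0_points)
  if (is.null(c_l_delta_values)) c_l_delta_values <- def$c_l_delta
  if (is.null(np_values)) np_values <- def$np_value
  cells <- expand.grid(c_l0 = grid_cl0, c_l_delta = c_l_delta_values,
                       np_value = np_values, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- scenario_config(family, scenario, c_l0 = cells$c_l0[i],
                           c_l_delta = cells$c_l_delta[i],
                           np_value = cells$np_value[i],
                           constellation = constellation, reps = reps,
                           seed = (seed + i) %% .Machine$integer.max, ...)
    row <- tryCatch(run_scenario(cfg, methods = methods), error = function(e) {
      warning(sprintf("cell %d (c_l0 = %g) failed: %s", i, cells$c_l0[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  merge_metric_rows(rows)
}

## rbind metrics rows with differing column sets (infeasible rows are short).
merge_metric_rows <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    for (m in setdiff(cols, names(r))) r[[m]] <- NA
    r[cols]
  }))
  rownames(out) <- NULL
  out
}

#' Maximum performance gap between two methods over a sweep
#'
#' The study's summary statistic: the maximum, over the feasible cells of a
#' severity sweep, of the difference between two methods' rejection (or
#' equivalence) proportions, in percentage points.
#'
#' @param table a metrics table from [sweep_grid()].
#' @param method_a,method_b column names (e.g. `"reject_welch_trans"`).
#' @return maximum of `100 * (a - b)` over feasible rows.
#' @export
max_gap <- function(table, method_a, method_b) {
  t <- table[!table$infeasible, , drop = FALSE]
  if (nrow(t) == 0) stop("no feasible cells in the slice", call. = FALSE)
  for (m in c(method_a, method_b))
    if (!m %in% names(t) || all(is.na(t[[m]])))
      stop("method column missing from the table: ", m, call. = FALSE)
  max(100 * (t[[method_a]] - t[[method_b]]))
}
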