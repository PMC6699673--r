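#' TOST calibration point of a severity range
#'
#' The equivalence margins are fixed across the `c_l` sweep and anchored at
#' the severity value located 3/4 of the way between the lower and the upper
#' bound of the family's `c_l` range (a weak-CFE reference point).
#'
#' @param c_l_range numeric length-2 range (may be decreasing, as for the
#'   Wald drift axis).
#' @return `lower + 0.75 * (upper - lower)`.
#' @examples
#' tost_calibration_point(c(-4, 4))  # 2
#' @export
tost_calibration_point <- function(c_l_range) {
  stopifnot(length(c_l_range) == 2, all(is.finite(c_l_range)))
  c_l_range[1] + 0.75 * (c_l_range[2] - c_l_range[1])
}

#' Calibrate the TOST equivalence margin for a family
#'
#' Simulates two groups at the calibration severity `c_l*` (see
#' [tost_calibration_point()]) and `c_l* + c_l_delta`, with `mc_size`
#' samples per group, and records the absolute (possibly transformed) mean
#' difference; the margin is the median over `reps` independent repetitions.
#' Separate margins are produced for raw and transformed data.
#'
#' If `c_l*` (or its offset partner) is infeasible for the family the
#' calibration point is clipped toward feasibility with a warning.
#'
#' @param family family tag.
#' @param c_l_delta group-difference offset used in the sweep.
#' @param np_value nuisance value (see [family_defaults()]).
#' @param mc_size Monte-Carlo samples per group (study value: 5000).
#' @param reps number of independent difference estimates whose median is
#'   taken (default 101).
#' @param c_l_range override the family's `c_l` range.
#' @param c_u,c_v,thresholds forwarded to [family_template()].
#' @param seed optional seed.
#' @return list with `raw` and `trans` margins and the calibration point
#'   `c_l_star`.
#' @export
calibrate_tost_threshold <- function(family, c_l_delta,
                                     np_value = family_defaults(family)$np_value,
                                     mc_size = 5000, reps = 101,
                                     c_l_range = NULL, c_u = NULL, c_v = 0.8,
                                     thresholds = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  def <- family_defaults(family)
  if (is.null(c_l_range)) c_l_range <- def$c_l_range
  star <- tost_calibration_point(c_l_range)
  cu_eff <- if (is.null(c_u))
    switch(family, beta = -0.2, betabinomial = -0.3, NULL) else c_u
  cn_eff <- if (family == "betaprime") np_value else NULL
  feasible_pair <- function(s)
    cfe_feasible(family, s, c_u = cu_eff, c_n = cn_eff) &&
    cfe_feasible(family, s + c_l_delta, c_u = cu_eff, c_n = cn_eff)
  if (!feasible_pair(star)) {
    ## walk the calibration point toward the severe end until feasible
    lo <- min(c_l_range); hi <- max(c_l_range)
    cand <- seq(star, lo, length.out = 200)
    ok <- which(vapply(cand, feasible_pair, logical(1)))
    if (!length(ok))
      stop("no feasible TOST calibration point in the c_l range", call. = FALSE)
    star <- cand[ok[1]]
    warning(sprintf("TOST calibration point clipped to %.4g for feasibility",
                    star), call. = FALSE)
  }
  pa <- family_template(family, c_l = star, np_value = np_value, c_u = c_u,
                        c_v = c_v, thresholds = thresholds)
  pb <- family_template(family, c_l = star + c_l_delta, np_value = np_value,
                        c_u = c_u, c_v = c_v, thresholds = thresholds)
  na <- natural_params(pa); nb <- natural_params(pb)
  tr <- default_transform(family)
  nlev <- transform_levels(pa)
  d_raw <- d_trans <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- cfe_sample(pa, mc_size, native = na)
    y <- cfe_sample(pb, mc_size, native = nb)
    d_raw[i] <- abs(mean(x) - mean(y))
    d_trans[i] <- abs(mean(apply_transform(tr, x, n_levels = nlev)) -
                        mean(apply_transform(tr, y, n_levels = nlev)))
  }
  list(raw = stats::median(d_raw), trans = stats::median(d_trans),
       c_l_star = star)
}
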