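#' Transformation specifications for the "transformed-data" test variants
#'
#' The battery compares each parametric method on raw data with the same
#' method on log- or logit-transformed data.  One bound (generalized gamma,
#' Wald, beta prime) calls for the log; two bounds (beta, beta-binomial,
#' ordered logistic) for the logit.  Bounded integer outcomes are first
#' mapped into the open unit interval by `(y + shift) / (n + 2 * shift)`, a
#' symmetric continuity correction that keeps all images strictly interior.
#'
#' @param kind `"identity"`, `"log"` or `"logit"`.
#' @param discrete_map map bounded integers `0..n` into (0, 1) before the
#'   logit.
#' @param shift continuity-correction constant for the discrete map
#'   (default 0.5, giving `(y + 0.5) / (n + 1)`).
#' @return an object of class `"transform_spec"`.
#' @export
transform_spec <- function(kind = c("identity", "log", "logit"),
                           discrete_map = FALSE, shift = 0.5) {
  kind <- match.arg(kind)
  if (discrete_map && kind != "logit")
    stop("'discrete_map' only applies to the logit transform", call. = FALSE)
  if (shift <= 0) stop("'shift' must be positive", call. = FALSE)
  structure(list(kind = kind, discrete_map = discrete_map, shift = shift),
            class = "transform_spec")
}

#' Default transform for a CFE family
#'
#' @param family family tag as in [cfe_params()].
#' @return a [transform_spec()]: log for the one-bound families, logit for
#'   the doubly bounded ones (via the discrete map for beta-binomial and
#'   ordered logistic outcomes).
#' @export
default_transform <- function(family) {
  switch(family,
    gengamma = , wald = , betaprime = transform_spec("log"),
    beta = transform_spec("logit"),
    betabinomial = , olrm = transform_spec("logit", discrete_map = TRUE),
    stop("unknown family: ", family, call. = FALSE))
}

#' Apply a transformation to a sample
#'
#' @param spec a [transform_spec()].
#' @param values numeric vector.
#' @param n_levels integer maximum of the discrete outcome (required when
#'   `spec$discrete_map` is set): the beta-binomial trial count, or
#'   `n_levels - 1` categories coded `0..n_levels-1` for the ordered
#'   logistic model map with its own maximum.
#' @return transformed vector; domain violations name the first offending
#'   index.
#' @examples
#' apply_transform(transform_spec("logit"), 0.5)  # 0
#' @export
apply_transform <- function(spec, values, n_levels = NULL) {
  stopifnot(inherits(spec, "transform_spec"))
  switch(spec$kind,
    identity = values,
    log = {
      bad <- which(values <= 0)
      if (length(bad))
        stop(sprintf("log transform: non-positive value at index %d", bad[1]),
             call. = FALSE)
      log(values)
    },
    logit = {
      if (spec$discrete_map) {
        if (is.null(n_levels))
          stop("'n_levels' is required for the discrete map", call. = FALSE)
        values <- (values + spec$shift) / (n_levels + 2 * spec$shift)
      }
      bad <- which(values <= 0 | values >= 1)
      if (length(bad))
        stop(sprintf("logit transform: value outside (0,1) at index %d",
                     bad[1]), call. = FALSE)
      log(values / (1 - values))
    })
}

## Integer maximum used by the discrete map for a family's outcomes.
transform_levels <- function(params) {
  switch(params$family,
    betabinomial = params$n_levels,
    olrm = params$n_levels - 1L,
    NULL)
}
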