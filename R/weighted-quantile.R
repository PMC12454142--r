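#' Weighted quantile (lower-value convention)
#'
#' Quantile of a set of values in which each value carries a nonnegative
#' weight — here, per-kg extinction impacts weighted by the production mass
#' they represent. Uses the lower-value (type-1, no interpolation)
#' convention: the result is the smallest value `v` whose cumulative weight
#' reaches `q` times the total weight. With integer weights this is exactly
#' the plain type-1 quantile of the sample in which each value is repeated
#' `weight` times, which keeps the estimator stable under rescaling of the
#' weights.
#'
#' With two countries producing 100 and 3 units, the weighted median is the
#' larger producer's value: the half-weight point falls inside its mass.
#'
#' @param values numeric vector.
#' @param weights nonnegative weights, same length as `values`; at least one
#'   must be positive.
#' @param q quantile(s) in \[0, 1\] (may be a vector).
#' @return numeric vector, one element per `q`.
#' @examples
#' weighted_quantile(c(1, 2, 3), c(1, 1, 1), 0.5)        # 2
#' weighted_quantile(c(5, 9), c(100, 3), 0.5)            # 5
#' @export
weighted_quantile <- function(values, weights, q) {
  if (length(values) != length(weights))
    stop("`values` and `weights` must have the same length", call. = FALSE)
  if (length(values) == 0L) stop("no values supplied", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("q must lie in [0, 1]", call. = FALSE)
  keep <- weights > 0
  if (!any(keep)) stop("all weights are zero", call. = FALSE)
  v <- values[keep]; w <- weights[keep]
  ord <- order(v)
  v <- v[ord]; w <- w[ord]
  cw <- cumsum(w)
  total <- cw[length(cw)]
  vapply(q, function(qi) {
    if (qi == 0) return(v[1L])
    v[which(cw >= qi * total)[1L]]
  }, numeric(1))
}
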