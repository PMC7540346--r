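#' Soft-thresholding (proximal operator of the l1 norm)
#'
#' `soft_threshold(v, t)[i] = sign(v[i]) * max(|v[i]| - t, 0)`.
#'
#' @param v numeric vector.
#' @param t threshold, a single nonnegative number.
#' @return Shrunk vector, same length as `v`.
#' @export
soft_threshold <- function(v, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("`t` must be a single nonnegative number")
  sign(v) * pmax(abs(v) - t, 0)
}

#' Exact 1-D total-variation proximal operator
#'
#' Solves `argmin_s 0.5 * ||y - s||^2 + lam * ||D s||_1` (D = first-order
#' difference) exactly with a direct taut-string-class algorithm; the
#' minimizer is unique by strong convexity.  With `lam = 0` the input is
#' returned unchanged; for `lam` at least half the total oscillation the
#' solution collapses to the mean of `y`.
#'
#' @param y numeric vector (finite).
#' @param lam nonnegative total-variation weight.
#' @return The exact minimizer, same length as `y`.
#' @examples
#' tv_prox(c(0, 4), 1)   # c(1, 3): endpoints move in by lam
#' @export
tv_prox <- function(y, lam) {
  y <- as.numeric(y)
  if (!all(is.finite(y))) stop("`y` must be finite")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0)
    stop("`lam` must be a single nonnegative number")
  if (length(y) == 0L) return(y)
  .tv_prox_cpp(y, lam)
}
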