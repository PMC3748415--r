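#' Lp penalty of a weight vector
#'
#' The regularizer of the Lp-SVM objective,
#' \eqn{\frac{1}{2}\sum_j |w_j|^p}. For p = 2 this is the usual ridge
#' penalty; for 0 < p < 1 it is the bridge penalty, a quasi-smooth
#' surrogate of the number of nonzero coefficients.
#'
#' @param w Numeric weight vector (finite).
#' @param p Norm exponent in (0, 2].
#' @return `0.5 * sum(abs(w)^p)`.
#' @export
#' @examples
#' lp_penalty(c(2, -2), 2)   # 4
#' lp_penalty(c(0, 0, 0), 0.5) # 0
lp_penalty <- function(w, p) {
  check_p(p)
  w <- as.numeric(w)
  if (!all(is.finite(w))) stop("'w' contains non-finite entries", call. = FALSE)
  0.5 * sum(abs(w)^p)
}

#' Diagonal reweighting vector
#'
#' Computes the smoothed reweighting diagonal
#' \eqn{v_j = (|w_j| + \epsilon)^{p-2}} used to turn the nonconvex Lp
#' penalty into a sequence of weighted quadratic penalties. The smoother
#' `epsilon` keeps the weight finite when a coordinate reaches zero (for
#' p < 2 the unsmoothed weight diverges there).
#'
#' @inheritParams lp_penalty
#' @param epsilon Smoother, strictly positive.
#' @return Positive numeric vector of length `length(w)`.
#' @export
#' @examples
#' reweight_diag(c(-3, 0.5), 2, 1e-8)  # exactly 1, 1
#' reweight_diag(0.5, 1, 1e-12)        # ~ 2
reweight_diag <- function(w, p, epsilon) {
  check_p(p)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("'epsilon' must be a single positive number", call. = FALSE)
  }
  w <- as.numeric(w)
  if (!all(is.finite(w))) stop("'w' contains non-finite entries", call. = FALSE)
  (abs(w) + epsilon)^(p - 2)
}
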