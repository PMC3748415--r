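#' Fitting control parameters
#'
#' Collects the tunable parameters of the iteratively reweighted Lp-SVM
#' fit. Defaults follow common practice for reweighting schemes and SMO
#' solvers; see the package vignette for the reasoning behind each.
#'
#' @param epsilon Reweighting smoother, > 0. The diagonal weights are
#'   \eqn{(|w_j| + \epsilon)^{p-2}}; `epsilon` bounds the weight of a
#'   zeroed coordinate (at `1e-8` a dead feature gets weight about
#'   `1e-8^(p-2)`, effectively removing it from the next QP without a
#'   division by zero).
#' @param box_c Box constraint C on the dual coefficients, > 0. `Inf`
#'   requests a hard margin and errors on non-separable data; the default
#'   10 is a soft margin suitable for overlapping classes.
#' @param outer_tol Outer convergence threshold on the relative change
#'   `||w_new - w|| / max(1, ||w||)`.
#' @param max_outer_iters Cap on outer reweighting iterations.
#' @param smo_tol KKT-violation tolerance for the inner SMO solver.
#' @param max_smo_passes Cap on SMO pair updates per inner solve.
#' @param support_threshold Dual coefficients above this define the
#'   support set S used for the bias.
#' @param feature_threshold Relative weight cutoff: feature j is selected
#'   when `|w_j| > feature_threshold * max(|w|)`. The default 0.1 is an
#'   order-of-magnitude rule: a feature counts as retained when its weight
#'   is within a factor of ten of the largest. It remains meaningful for
#'   dense fits (p = 2), where a near-zero cutoff would select every
#'   feature.
#' @return A list of class `irwp_control`.
#' @export
irwp_control <- function(epsilon = 1e-8,
                         box_c = 10,
                         outer_tol = 1e-4,
                         max_outer_iters = 50L,
                         smo_tol = 1e-6,
                         max_smo_passes = 1000000L,
                         support_threshold = 1e-8,
                         feature_threshold = 0.1) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(box_c), length(box_c) == 1L, box_c > 0,
            is.numeric(outer_tol), outer_tol > 0,
            is.numeric(max_outer_iters), max_outer_iters >= 1,
            is.numeric(smo_tol), smo_tol > 0,
            is.numeric(max_smo_passes), max_smo_passes >= 1,
            is.numeric(support_threshold), support_threshold >= 0,
            is.numeric(feature_threshold), feature_threshold >= 0)
  structure(list(epsilon = epsilon,
                 box_c = box_c,
                 outer_tol = outer_tol,
                 max_outer_iters = as.integer(max_outer_iters),
                 smo_tol = smo_tol,
                 max_smo_passes = as.integer(max_smo_passes),
                 support_threshold = support_threshold,
                 feature_threshold = feature_threshold),
            class = "irwp_control")
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 2) {
    stop_irwp(sprintf("p must lie in (0, 2], got %s", format(p)),
              class = "irwp_usage_error")
  }
  p
}

# classed conditions so the CLI can map causes to distinct exit codes
stop_irwp <- function(msg, class = "irwp_error", call. = FALSE) {
  stop(structure(class = c(class, "irwp_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# run code under a temporary RNG state; NULL seed leaves the stream alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_irwp("seed must be a single finite number", class = "irwp_usage_error")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
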