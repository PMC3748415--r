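# Weighted dual QP and its SMO solver.
#
# One outer iteration of the reweighted fit solves
#   min_a 1/2 a' Q a - 1' a,  0 <= a_i <= C,  sum_i a_i y_i = 0
# with Q_ij = y_i y_j x_i' V^{-1} x_j and V = diag(v) the current
# reweighting diagonal. Q is formed densely (in-scope problems have at
# most a few thousand samples) and handed to the compiled SMO loop; the
# pure-R working-set primitives below share its semantics and are used on
# small problems and in tests.

#' Build the label-signed Gram matrix of the weighted dual
#'
#' @param x Sample-by-feature matrix.
#' @param y Labels in -1/+1.
#' @param v Positive reweighting diagonal, length `ncol(x)`.
#' @return Dense m-by-m matrix `Q` with
#'   `Q[i, j] = y[i] y[j] sum_k x[i, k] x[j, k] / v[k]`.
#' @export
dual_q_matrix <- function(x, y, v) {
  x <- as.matrix(x)
  v <- as.numeric(v)
  if (length(v) != ncol(x)) stop("length(v) must equal ncol(x)", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("'v' must be strictly positive and finite", call. = FALSE)
  }
  xs <- x * rep(sqrt(1 / v), each = nrow(x))
  tcrossprod(xs) * tcrossprod(as.numeric(y))
}

#' Solve one weighted SVM dual QP
#'
#' Minimizes `0.5 a'Qa - sum(a)` over `0 <= a <= box_c` with
#' `sum(a * y) = 0`, by sequential minimal optimization with
#' maximum-violating-pair working sets.
#'
#' @param x Sample-by-feature matrix (or an [lp_dataset()], in which case
#'   `y` is ignored).
#' @param y Labels in -1/+1; both classes must be present.
#' @param v Positive reweighting diagonal (length `ncol(x)`).
#' @param control An [irwp_control()]; uses `box_c`, `smo_tol`,
#'   `max_smo_passes`.
#' @param alpha0 Optional feasible starting point for warm starts (box-
#'   and equality-feasible, e.g. the solution of a previous reweighting
#'   iteration); default is a cold start at zero. The recovered primal
#'   weights do not depend on the start, only solver effort does.
#' @return A list of class `irwp_dual`: `alpha`, `dual_objective`,
#'   `n_passes`, `converged`, `max_kkt_violation`.
#' @export
solve_weighted_dual <- function(x, y = NULL, v, control = irwp_control(),
                                alpha0 = NULL) {
  d <- as_xy(x, y)
  check_two_classes(d$y)
  # features whose inverse reweight is numerically zero contribute less
  # than ~1e-14 relative to Q; dropping them is a no-op at smo_tol scale
  inv_v <- 1 / as.numeric(v)
  if (length(inv_v) != ncol(d$x)) {
    stop("length(v) must equal ncol(x)", call. = FALSE)
  }
  if (any(!is.finite(inv_v)) || any(inv_v <= 0)) {
    stop("'v' must be strictly positive and finite", call. = FALSE)
  }
  act <- which(inv_v > 1e-14 * max(inv_v))
  xs <- d$x[, act, drop = FALSE] *
    rep(sqrt(inv_v[act]), each = nrow(d$x))
  q <- tcrossprod(xs) * tcrossprod(d$y)
  if (is.null(alpha0)) alpha0 <- numeric(0)
  sol <- smo_solve_cpp(q, d$y, control$box_c, control$smo_tol,
                       control$max_smo_passes, alpha0)
  if (sol$status == 2L) {
    stop_irwp(paste("hard-margin dual is unbounded: the data are not linearly",
                    "separable; set a finite box_c in irwp_control()"),
              class = "irwp_data_error")
  }
  if (!sol$converged) {
    warning(sprintf("SMO did not converge in %d pair updates (KKT violation %.3g)",
                    sol$n_passes, sol$max_kkt_violation), call. = FALSE)
  }
  structure(sol[c("alpha", "dual_objective", "n_passes", "converged",
                  "max_kkt_violation")],
            class = "irwp_dual")
}

#' Maximum-violating-pair working-set selection
#'
#' Pure-R reference for the working-set rule used by the compiled solver:
#' over the "up" set take the index maximizing `-y * grad`, over the
#' "down" set the index minimizing it; the pair violates the KKT
#' conditions when the gap exceeds `tol`.
#'
#' @param alpha Current dual vector.
#' @param grad Current dual gradient `Q alpha - 1`.
#' @param y Labels in -1/+1.
#' @param box_c Box constraint (may be `Inf`).
#' @param tol Violation tolerance.
#' @return Integer vector `c(i, j)`, or `NULL` when no pair violates by
#'   more than `tol` (convergence).
#' @export
max_violating_pair <- function(alpha, grad, y, box_c, tol) {
  v <- -y * grad
  up <- ifelse(y > 0, alpha < box_c, alpha > 0)
  down <- ifelse(y > 0, alpha > 0, alpha < box_c)
  if (!any(up) || !any(down)) return(NULL)
  i <- which(up)[which.max(v[up])]
  j <- which(down)[which.min(v[down])]
  if (v[i] - v[j] <= tol) return(NULL)
  c(i, j)
}

#' Closed-form update of one working pair
#'
#' Optimizes the dual over `(alpha[i], alpha[j])` along the
#' equality-feasible line, clipped to the box; `sum(alpha * y)` is
#' preserved exactly and the dual objective never increases. Non-positive
#' pair curvature (duplicate points) degenerates to the better endpoint
#' via the same clip.
#'
#' @inheritParams max_violating_pair
#' @param q Dense dual matrix from [dual_q_matrix()].
#' @param i,j Working pair indices, `i != j`.
#' @return List with updated `alpha` and `grad`.
#' @export
two_variable_update <- function(alpha, grad, q, y, box_c, i, j) {
  stopifnot(i != j)
  curv <- q[i, i] + q[j, j] - 2 * y[i] * y[j] * q[i, j]
  if (curv <= 0) curv <- 1e-12
  viol <- (-y[i] * grad[i]) - (-y[j] * grad[j])
  if (viol <= 0) return(list(alpha = alpha, grad = grad))
  lin <- y[i] * alpha[i] + y[j] * alpha[j]
  ai <- alpha[i] + y[i] * viol / curv
  ai <- min(max(ai, 0), box_c)
  aj <- y[j] * (lin - y[i] * ai)
  aj <- min(max(aj, 0), box_c)
  ai <- y[i] * (lin - y[j] * aj)
  dai <- ai - alpha[i]
  daj <- aj - alpha[j]
  alpha[i] <- ai
  alpha[j] <- aj
  grad <- grad + q[, i] * dai + q[, j] * daj
  list(alpha = alpha, grad = grad)
}

#' Recover primal weights from a dual solution
#'
#' @param x Sample-by-feature matrix (or [lp_dataset()]).
#' @param y Labels in -1/+1.
#' @param alpha Dual coefficients, length `nrow(x)`.
#' @param v Positive reweighting diagonal, length `ncol(x)`.
#' @return Weight vector `w` with `w_j = (1 / v_j) * sum_i alpha_i y_i x_ij`.
#' @export
primal_from_dual <- function(x, y = NULL, alpha, v) {
  d <- as_xy(x, y)
  if (length(alpha) != nrow(d$x)) {
    stop("length(alpha) must equal the number of samples", call. = FALSE)
  }
  if (length(v) != ncol(d$x)) {
    stop("length(v) must equal the number of features", call. = FALSE)
  }
  drop(crossprod(d$x, alpha * d$y)) / as.numeric(v)
}

#' Bias from the support set
#'
#' The support set is `S = {i : alpha_i > support_threshold}`; by
#' complementary slackness its points sit on the margin, so the bias is
#' recovered as the mean of `w'x_k - y_k` over `k in S`.
#'
#' @param x Sample-by-feature matrix (or [lp_dataset()]).
#' @param y Labels in -1/+1.
#' @param w Primal weight vector.
#' @param alpha Dual coefficients.
#' @param support_threshold Cutoff defining S.
#' @return The scalar bias `b`.
#' @export
compute_bias <- function(x, y = NULL, w, alpha, support_threshold = 1e-8) {
  d <- as_xy(x, y)
  s <- which(alpha > support_threshold)
  if (length(s) == 0L) {
    stop("empty support set: no alpha exceeds support_threshold", call. = FALSE)
  }
  mean(drop(d$x[s, , drop = FALSE] %*% w) - d$y[s])
}
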