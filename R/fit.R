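#' Fit an iteratively reweighted Lp-norm SVM
#'
#' Solves the linear Lp-regularized SVM
#' \deqn{\min_w \tfrac{1}{2}\|w\|_p^p \quad s.t.\quad y_i(w^\top x_i - b) \ge 1}
#' (soft-margin when `box_c` is finite) by iterative reweighting. Starting
#' from `w = 1` (so the first inner solve is the plain L2 SVM), each outer
#' iteration forms the diagonal `v = (|w| + epsilon)^(p-2)`, solves the
#' weighted dual QP by SMO, recovers `w` and the bias `b`, and stops when
#' the relative change in `w` drops below `outer_tol`. For p = 2 the
#' reweighting is the identity and the fit reduces to the ordinary L2 SVM
#' in at most two outer iterations; for p < 2 coordinates are progressively
#' down-weighted and, for p < 1, driven to (numerical) zero, yielding a
#' sparse weight vector.
#'
#' Training data are expected standardized (zero mean, unit variance per
#' feature); see [standardize()].
#'
#' @param x Sample-by-feature matrix, or an [lp_dataset()].
#' @param y Labels in -1/+1 (ignored when `x` is an `lp_dataset`).
#' @param p Norm exponent in (0, 2].
#' @param control An [irwp_control()].
#' @return An object of class `irwp_svm` with elements `weights`, `bias`,
#'   `p`, `support_indices`, `alpha`, `n_outer_iters`, `weight_trajectory`
#'   (one weight vector per outer iteration), `converged`, `dual`
#'   (diagnostics of the final inner solve) and `control`.
#' @seealso [predict.irwp_svm()], [decision_function()],
#'   [selected_features()]
#' @export
#' @examples
#' set.seed(1)
#' d <- generate_weston(200, seed = 1)
#' std <- standardize(d)
#' fit <- irwp_svm(std$train, p = 0.8)
#' fit
#' selected_features(fit)
irwp_svm <- function(x, y = NULL, p = 0.8, control = irwp_control()) {
  check_p(p)
  d <- as_xy(x, y)
  check_two_classes(d$y)
  n <- ncol(d$x)
  w <- rep(1, n)
  traj <- vector("list", control$max_outer_iters)
  converged <- FALSE
  sol <- NULL
  b <- NA_real_
  iter <- 0L
  alpha <- NULL
  for (t in seq_len(control$max_outer_iters)) {
    iter <- t
    v <- reweight_diag(w, p, control$epsilon)
    sol <- solve_weighted_dual(d$x, d$y, v, control, alpha0 = alpha)
    alpha <- sol$alpha
    w_new <- primal_from_dual(d$x, d$y, sol$alpha, v)
    b <- compute_bias(d$x, d$y, w_new, sol$alpha, control$support_threshold)
    traj[[t]] <- w_new
    delta <- sqrt(sum((w_new - w)^2)) / max(1, sqrt(sum(w^2)))
    w <- w_new
    if (delta < control$outer_tol) {
      converged <- TRUE
      break
    }
  }
  names(w) <- colnames(d$x)
  structure(list(weights = w,
                 bias = b,
                 p = p,
                 support_indices = which(sol$alpha > control$support_threshold),
                 alpha = sol$alpha,
                 n_outer_iters = iter,
                 weight_trajectory = traj[seq_len(iter)],
                 converged = converged,
                 dual = sol,
                 control = control,
                 scaler = NULL,
                 label_map = NULL),
            class = "irwp_svm")
}

#' @export
print.irwp_svm <- function(x, ...) {
  cat(sprintf("Lp-SVM fit (p = %g)\n", x$p))
  cat(sprintf("  %d features, %d selected; %d support vectors\n",
              length(x$weights), length(selected_features(x)),
              length(x$support_indices)))
  cat(sprintf("  bias %.6g; %d outer iterations (%s)\n", x$bias,
              x$n_outer_iters,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.irwp_svm <- function(object, ...) {
  c(bias = object$bias, object$weights)
}

#' Signed margin of samples under a fitted model
#'
#' Returns the real-valued discriminant `w'x - b`; its sign is the
#' predicted class.
#'
#' @param model A fitted [irwp_svm()].
#' @param x Numeric vector (one sample) or matrix (samples in rows) with
#'   `length(model$weights)` features. Raw features: the persisted scaler,
#'   if any, is applied first.
#' @return Numeric vector of margins, one per sample.
#' @export
decision_function <- function(model, x) {
  stopifnot(inherits(model, "irwp_svm"))
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(model$weights)) {
    stop_irwp(sprintf("feature dimension mismatch: model has %d, input has %d",
                      length(model$weights), ncol(x)),
              class = "irwp_data_error")
  }
  if (!is.null(model$scaler)) x <- apply_scaler(model$scaler, x)
  drop(x %*% model$weights - model$bias)
}

#' Predict class labels
#'
#' @param object A fitted [irwp_svm()].
#' @param newdata Sample matrix (or vector for one sample), or an
#'   [lp_dataset()].
#' @param type `"class"` for -1/+1 labels (the default; a margin of
#'   exactly zero maps to +1), `"margin"` for the raw discriminant.
#' @param ... Unused.
#' @return Numeric vector of -1/+1 labels, or margins.
#' @export
predict.irwp_svm <- function(object, newdata, type = c("class", "margin"),
                             ...) {
  type <- match.arg(type)
  if (inherits(newdata, "lp_dataset")) newdata <- newdata$x
  f <- decision_function(object, newdata)
  if (type == "margin") return(f)
  ifelse(f >= 0, 1, -1)
}

#' Indices of the selected features
#'
#' A feature is retained when its weight magnitude exceeds a small
#' fraction of the largest one: `|w_j| > threshold * max(|w|)`. With the
#' bridge penalty (p < 1) the discarded weights are numerically zero, so
#' the selection is insensitive to the threshold over several orders of
#' magnitude.
#'
#' @param model A fitted [irwp_svm()].
#' @param feature_threshold Relative cutoff; defaults to the one the model
#'   was fitted with.
#' @return Sorted integer vector of selected feature indices.
#' @export
selected_features <- function(model, feature_threshold = NULL) {
  stopifnot(inherits(model, "irwp_svm"))
  if (is.null(feature_threshold)) {
    feature_threshold <- model$control$feature_threshold
  }
  aw <- abs(model$weights)
  mx <- max(aw)
  if (mx == 0) stop("all weights are zero; no features to select", call. = FALSE)
  which(aw > feature_threshold * mx)
}
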