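# Flat-JSON model persistence. Doubles are written at full precision
# (digits = NA) so a round trip reproduces predictions bit for bit.

#' Write a fitted model to a JSON file
#'
#' Persists weights, bias, p, support set, control parameters,
#' convergence diagnostics and, when present, the standardization scaler
#' and label mapping. [read_irwp_model()] restores an object whose
#' predictions are bit-identical to the original's.
#'
#' @param model A fitted [irwp_svm()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_irwp_model <- function(model, path) {
  stopifnot(inherits(model, "irwp_svm"))
  payload <- list(
    format = "irwpsvm-model",
    format_version = 1L,
    p = model$p,
    weights = unname(model$weights),
    feature_names = names(model$weights),
    bias = model$bias,
    support_indices = as.integer(model$support_indices),
    n_outer_iters = model$n_outer_iters,
    converged = model$converged,
    control = unclass(model$control),
    dual = list(dual_objective = model$dual$dual_objective,
                n_passes = model$dual$n_passes,
                converged = model$dual$converged,
                max_kkt_violation = model$dual$max_kkt_violation),
    scaler = if (!is.null(model$scaler)) {
      list(center = unname(model$scaler$center),
           scale = unname(model$scaler$scale))
    },
    label_map = if (!is.null(model$label_map)) {
      list(levels = names(model$label_map),
           codes = unname(model$label_map))
    }
  )
  # I(17) = 17 significant digits, enough to reproduce doubles bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from a JSON file
#'
#' @param path Path written by [write_irwp_model()].
#' @return An object of class `irwp_svm`.
#' @export
read_irwp_model <- function(path) {
  if (!file.exists(path)) {
    stop_irwp(sprintf("cannot read '%s': no such file", path),
              class = "irwp_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "irwpsvm-model")) {
    stop_irwp(sprintf("'%s' is not an irwpsvm model file", path),
              class = "irwp_io_error")
  }
  ctl <- do.call(irwp_control, as.list(obj$control))
  w <- as.numeric(obj$weights)
  if (!is.null(obj$feature_names)) names(w) <- obj$feature_names
  scaler <- NULL
  if (!is.null(obj$scaler)) {
    scaler <- structure(list(center = as.numeric(obj$scaler$center),
                             scale = as.numeric(obj$scaler$scale)),
                        class = "lp_scaler")
  }
  label_map <- NULL
  if (!is.null(obj$label_map)) {
    label_map <- as.numeric(obj$label_map$codes)
    names(label_map) <- obj$label_map$levels
  }
  structure(list(weights = w,
                 bias = as.numeric(obj$bias),
                 p = as.numeric(obj$p),
                 support_indices = as.integer(obj$support_indices),
                 alpha = NULL,
                 n_outer_iters = as.integer(obj$n_outer_iters),
                 weight_trajectory = NULL,
                 converged = isTRUE(obj$converged),
                 dual = obj$dual,
                 control = ctl,
                 scaler = scaler,
                 label_map = label_map),
            class = "irwp_svm")
}
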