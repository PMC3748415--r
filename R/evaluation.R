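# Evaluation criteria and the simulation experiment harness.
#
# Two criteria, both in percent: prediction error on a validation split,
# and feature-selection error against the generator's known relevant set.
# The experiment grid fits the model at each p on freshly generated
# Weston data, one dataset per trial, and aggregates means and SDs.

#' Validation prediction error rate
#'
#' @param model A fitted [irwp_svm()].
#' @param valid Validation [lp_dataset()] (nonempty).
#' @return Percentage of misclassified validation samples, in \[0, 100\].
#' @export
prediction_error_rate <- function(model, valid) {
  stopifnot(inherits(valid, "lp_dataset"))
  if (nrow(valid$x) == 0L) stop("empty validation set", call. = FALSE)
  yhat <- predict(model, valid$x)
  100 * mean(yhat != valid$y)
}

#' Feature-selection error rate
#'
#' Symmetric-difference error between the selected and the ground-truth
#' relevant feature sets, as a percentage of all features:
#' `100 * |selected XOR relevant| / n_features`. Zero iff the relevant set
#' is recovered exactly; a missed relevant feature and a false positive
#' each cost `100 / n_features`.
#'
#' @param selected Integer vector of selected feature indices.
#' @param relevant Integer vector of ground-truth relevant indices.
#' @param n_features Total number of features.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' feature_selection_error_rate(1:8, 1:6, 100) # 2: two false positives
feature_selection_error_rate <- function(selected, relevant, n_features) {
  selected <- unique(as.integer(selected))
  relevant <- unique(as.integer(relevant))
  idx <- c(selected, relevant)
  if (length(idx) && (any(idx < 1L) || any(idx > n_features))) {
    stop("feature indices out of range", call. = FALSE)
  }
  sym <- length(setdiff(selected, relevant)) + length(setdiff(relevant, selected))
  100 * sym / n_features
}

# deterministic per-trial sub-seed, kept inside 32-bit integer range
trial_seed <- function(master_seed, trial) {
  as.integer((as.numeric(master_seed) * 100003 + as.numeric(trial) * 999331) %%
               2147483629)
}

#' Run the synthetic simulation grid
#'
#' For each trial: generate `n_samples` Weston samples under a
#' trial-specific sub-seed, split into training and validation for each
#' requested training size, standardize (scaler fitted on the training
#' part only), fit the Lp-SVM at each `p`, and record the validation
#' prediction error and the feature-selection error against the known
#' relevant set. Results are fully reproducible from
#' `(p_grid, train_sizes, trial_ids, seed)`.
#'
#' A failing fit is recorded as `NA` and excluded from the aggregation;
#' more than 10% failures abort the experiment.
#'
#' @param p_grid Numeric vector of norm exponents in (0, 2].
#' @param train_sizes Integer vector of training-set sizes; the rest of
#'   each dataset is the validation part.
#' @param n_trials Number of independent trials.
#' @param seed Master seed; trial t uses the sub-seed
#'   `(seed * 100003 + t * 999331) mod 2147483629`.
#' @param control An [irwp_control()].
#' @param n_samples Samples generated per trial (default 1000).
#' @param n_features Features per sample (default 100).
#' @param trial_ids Trial indices to run (default `1:n_trials`); running
#'   disjoint id ranges and combining with [combine_experiments()] equals
#'   one longer run.
#' @return An object of class `irwp_experiment`: list with `trials` (one
#'   row per trial x split x p: `trial`, `p`, `n_train`, `n_valid`,
#'   `prediction_error_pct`, `feature_selection_error_pct`, `n_selected`,
#'   `seed`) and `summary` (long format: `p`, `n_train`, `n_valid`,
#'   `metric`, `mean`, `sd`, `n_trials`).
#' @export
run_experiment <- function(p_grid, train_sizes, n_trials, seed,
                           control = irwp_control(),
                           n_samples = 1000L, n_features = 100L,
                           trial_ids = seq_len(n_trials)) {
  stopifnot(length(p_grid) >= 1L, n_trials >= 1L)
  for (p in p_grid) check_p(p)
  rows <- vector("list", length(trial_ids) * length(train_sizes) *
                   length(p_grid))
  k <- 0L
  n_failed <- 0L
  for (t in trial_ids) {
    ts <- trial_seed(seed, t)
    data <- generate_weston(n_samples, n_features = n_features, seed = ts)
    for (si in seq_along(train_sizes)) {
      n_train <- train_sizes[[si]]
      sp <- split_dataset(data, n_train, seed = ts + 7919L * si)
      std <- standardize(sp$train, list(sp$valid))
      valid <- std$others[[1L]]
      for (p in p_grid) {
        k <- k + 1L
        res <- tryCatch({
          fit <- irwp_svm(std$train, p = p, control = control)
          sel <- selected_features(fit)
          list(pe = prediction_error_rate(fit, valid),
               fse = feature_selection_error_rate(sel, data$relevant,
                                                  n_features),
               nsel = length(sel))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          n_failed <- n_failed + 1L
          message(sprintf("trial %d, n_train %d, p %g failed: %s",
                          t, n_train, p, conditionMessage(res)))
          res <- list(pe = NA_real_, fse = NA_real_, nsel = NA_integer_)
        }
        rows[[k]] <- data.frame(trial = t, p = p, n_train = n_train,
                                n_valid = n_samples - n_train,
                                prediction_error_pct = res$pe,
                                feature_selection_error_pct = res$fse,
                                n_selected = res$nsel, seed = ts)
      }
    }
  }
  trials <- do.call(rbind, rows)
  if (n_failed > 0.1 * nrow(trials)) {
    stop_irwp(sprintf("%d of %d fits failed (> 10%%); aborting experiment",
                      n_failed, nrow(trials)), class = "irwp_data_error")
  }
  new_experiment(trials)
}

new_experiment <- function(trials) {
  structure(list(trials = trials, summary = summarize_trials(trials)),
            class = "irwp_experiment")
}

summarize_trials <- function(trials) {
  long <- rbind(
    data.frame(trials[c("p", "n_train", "n_valid")],
               metric = "prediction_error",
               value = trials$prediction_error_pct),
    data.frame(trials[c("p", "n_train", "n_valid")],
               metric = "feature_selection_error",
               value = trials$feature_selection_error_pct),
    data.frame(trials[c("p", "n_train", "n_valid")],
               metric = "n_selected",
               value = as.numeric(trials$n_selected)))
  agg <- aggregate(value ~ p + n_train + n_valid + metric, data = long,
                   FUN = function(v) {
                     n <- sum(!is.na(v))
                     c(mean = mean(v, na.rm = TRUE),
                       sd = if (n < 2L) 0 else sd(v, na.rm = TRUE),
                       n = n)
                   },
                   na.action = stats::na.pass)
  out <- data.frame(agg[c("p", "n_train", "n_valid", "metric")],
                    mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"],
                    n_trials = as.integer(agg$value[, "n"]))
  out[order(out$metric, out$n_train, out$p), , drop = FALSE]
}

#' Combine experiment runs over disjoint trial ids
#'
#' @param ... `irwp_experiment` objects from [run_experiment()] with
#'   disjoint `trial_ids` under the same master seed and grid.
#' @return A single `irwp_experiment` with the pooled trials re-aggregated.
#' @export
combine_experiments <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1), "irwp_experiment")))
  new_experiment(do.call(rbind, lapply(parts, `[[`, "trials")))
}

#' @export
print.irwp_experiment <- function(x, ...) {
  cat(sprintf("<irwp_experiment> %d fits (%d trials x %d splits x %d p values)\n",
              nrow(x$trials), length(unique(x$trials$trial)),
              length(unique(x$trials$n_train)), length(unique(x$trials$p))))
  print(head(x$summary, 12L), row.names = FALSE)
  if (nrow(x$summary) > 12L) cat("  ...\n")
  invisible(x)
}

#' Write an experiment summary as tidy CSV
#'
#' Columns: `p`, `n_train`, `n_valid`, `metric`, `mean`, `sd`, `n_trials`.
#'
#' @param experiment An `irwp_experiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(experiment, path) {
  stopifnot(inherits(experiment, "irwp_experiment"))
  write.csv(experiment$summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select p on a validation split
#'
#' Fits the model at every `p` in the grid, evaluates the validation
#' prediction error, and returns the best `p`; ties go to the smaller `p`
#' (the sparser model).
#'
#' @param train,valid Standardized [lp_dataset()]s.
#' @param p_grid Candidate norm exponents.
#' @param control An [irwp_control()].
#' @return List with `p`, `model` (refit kept from the winning p),
#'   `errors` (named vector of validation errors per p).
#' @export
select_p <- function(train, valid, p_grid, control = irwp_control()) {
  stopifnot(length(p_grid) >= 1L)
  p_grid <- sort(as.numeric(p_grid))
  errs <- rep(NA_real_, length(p_grid))
  fits <- vector("list", length(p_grid))
  for (i in seq_along(p_grid)) {
    res <- tryCatch({
      fit <- irwp_svm(train, p = p_grid[i], control = control)
      list(fit = fit, err = prediction_error_rate(fit, valid))
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      fits[[i]] <- res$fit
      errs[i] <- res$err
    }
  }
  if (all(is.na(errs))) {
    stop_irwp("all fits failed across the p grid", class = "irwp_data_error")
  }
  best <- which.min(errs) # first minimum = smallest p on the sorted grid
  names(errs) <- format(p_grid)
  list(p = p_grid[best], model = fits[[best]], errors = errs)
}
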