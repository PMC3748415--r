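# Synthetic benchmark with known relevant features (Weston protocol).
#
# Six of n_features carry class signal, split over two blocks chosen by a
# 0.7/0.3 coin per sample; the rest are pure noise. Ground truth is known,
# so feature-selection error is measurable exactly.

#' Generate Weston-protocol synthetic data
#'
#' Each sample gets a label `y = -1/+1` with equal probability. With
#' probability `primary_block_prob` features 1-3 are drawn from
#' `y * N(3, 1)`, `y * N(2.2, 1)`, `y * N(1.4, 1)` and features 4-6 from
#' `N(0, 1)`; otherwise the two blocks swap roles. The remaining
#' `n_features - 6` features are `N(0, 20)` noise (variance 20). The block
#' coin is drawn independently of the label. Relevant ground truth is
#' features 1-6.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_features Total number of features (>= 6; default 100).
#' @param relevant_means Class-conditional means of the signal triplet.
#' @param primary_block_prob Probability that features 1-3 carry the
#'   signal for a given sample.
#' @param noise_var Variance of the noise features.
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   bit for bit and the caller's RNG stream is left untouched.
#' @return An [lp_dataset()] with `relevant = 1:6`.
#' @export
#' @examples
#' d <- generate_weston(100, seed = 42)
#' table(d$y)
generate_weston <- function(n_samples,
                            n_features = 100L,
                            relevant_means = c(3, 2.2, 1.4),
                            primary_block_prob = 0.7,
                            noise_var = 20,
                            seed = NULL) {
  if (n_samples < 2L) stop("n_samples must be at least 2", call. = FALSE)
  if (n_features < 6L) stop("n_features must be at least 6", call. = FALSE)
  stopifnot(length(relevant_means) == 3L,
            primary_block_prob >= 0, primary_block_prob <= 1,
            noise_var > 0)
  with_seed(seed, {
    m <- as.integer(n_samples)
    nf <- as.integer(n_features)
    y <- sample(c(-1, 1), m, replace = TRUE)
    primary <- runif(m) < primary_block_prob
    signal <- matrix(rnorm(3L * m, mean = outer(y, relevant_means)), m, 3L)
    inert <- matrix(rnorm(3L * m), m, 3L)
    x <- matrix(0, m, nf)
    x[primary, 1:3] <- signal[primary, , drop = FALSE]
    x[primary, 4:6] <- inert[primary, , drop = FALSE]
    x[!primary, 1:3] <- inert[!primary, , drop = FALSE]
    x[!primary, 4:6] <- signal[!primary, , drop = FALSE]
    if (nf > 6L) {
      x[, 7:nf] <- matrix(rnorm(m * (nf - 6L), sd = sqrt(noise_var)),
                          m, nf - 6L)
    }
    colnames(x) <- sprintf("f%03d", seq_len(nf))
    out <- lp_dataset(x, y, relevant = 1:6)
    # which block carried the signal, kept for generator diagnostics
    attr(out, "primary_block") <- primary
    out
  })
}

#' Standardize features on a training set
#'
#' Fits a per-feature affine transform on `train` (center to mean zero,
#' scale to unit standard deviation, SD with denominator m) and applies the
#' same transform to any further datasets, e.g. a validation split -- the
#' scaler is never refitted on them.
#'
#' @param train An [lp_dataset()] to fit the scaler on.
#' @param others List of further `lp_dataset`s to transform with the
#'   fitted scaler.
#' @return List with `train` (standardized), `others` (list, standardized)
#'   and `scaler` (class `lp_scaler`, reusable via [apply_scaler()]).
#' @export
standardize <- function(train, others = list()) {
  stopifnot(inherits(train, "lp_dataset"))
  x <- train$x
  center <- colMeans(x)
  dev <- sweep(x, 2, center)
  scale <- sqrt(colMeans(dev^2))
  bad <- which(scale < 1e-12)
  if (length(bad)) {
    stop_irwp(sprintf("zero-variance feature(s) in training data: %s",
                      paste(bad, collapse = ", ")),
              class = "irwp_data_error")
  }
  scaler <- structure(list(center = center, scale = scale),
                      class = "lp_scaler")
  tr <- lp_dataset(apply_scaler(scaler, x), train$y, train$relevant)
  oth <- lapply(others, function(d) {
    stopifnot(inherits(d, "lp_dataset"))
    lp_dataset(apply_scaler(scaler, d$x), d$y, d$relevant)
  })
  list(train = tr, others = oth, scaler = scaler)
}

#' Apply a fitted scaler
#'
#' @param scaler An `lp_scaler` from [standardize()].
#' @param x Matrix with the same number of features the scaler was fitted
#'   on.
#' @return The transformed matrix.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "lp_scaler"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$center)) {
    stop_irwp(sprintf("scaler fitted on %d features, input has %d",
                      length(scaler$center), ncol(x)),
              class = "irwp_data_error")
  }
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' Split a dataset into training and validation parts
#'
#' Seeded uniform split without replacement. If a draw leaves the training
#' part single-class the permutation is redrawn, up to 100 times.
#'
#' @param data An [lp_dataset()].
#' @param n_train Training-set size, `1 <= n_train < n_samples`.
#' @param seed Optional integer seed.
#' @return List with `train` and `valid` (`lp_dataset`s) and `train_idx`.
#' @export
split_dataset <- function(data, n_train, seed = NULL) {
  stopifnot(inherits(data, "lp_dataset"))
  m <- nrow(data$x)
  if (n_train < 1L || n_train >= m) {
    stop("n_train must satisfy 1 <= n_train < n_samples", call. = FALSE)
  }
  with_seed(seed, {
    idx <- NULL
    for (attempt in 1:100) {
      cand <- sample.int(m, n_train)
      if (length(unique(data$y[cand])) == 2L) {
        idx <- cand
        break
      }
    }
    if (is.null(idx)) {
      stop_irwp("could not draw a split with both classes in the training part",
                class = "irwp_data_error")
    }
    idx <- sort(idx)
    list(train = lp_dataset(data$x[idx, , drop = FALSE], data$y[idx],
                            data$relevant),
         valid = lp_dataset(data$x[-idx, , drop = FALSE], data$y[-idx],
                            data$relevant),
         train_idx = idx)
  })
}
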