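# Small fixtures built in code.

# one feature, one point per class, on the margin: alpha = (1/2, 1/2),
# w = 1, b = 0 by hand-solved KKT
toy_1d <- function() {
  lp_dataset(matrix(c(1, -1), 2, 1), c(1, -1))
}

# separable 4-point problem in 2-D, margin along the first coordinate
toy_2d <- function() {
  x <- rbind(c(2, 1), c(2.5, -1), c(-2, 0.5), c(-2.2, -0.8))
  lp_dataset(x, c(1, 1, -1, -1))
}

# overlapping 1-D classes: identical point with both labels, hence not
# linearly separable at any margin
toy_nonseparable <- function() {
  lp_dataset(matrix(c(1, 1, -1, 2), 4, 1), c(1, -1, -1, 1))
}

hard_margin_control <- function(...) irwp_control(box_c = Inf, ...)

# one standardized Weston train/valid pair, memoized per (seed, n, split)
weston_split_std <- local({
  cache <- new.env(parent = emptyenv())
  function(seed, n_samples = 1000, n_train = 500, n_features = 100) {
    key <- paste(seed, n_samples, n_train, n_features, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    d <- generate_weston(n_samples, n_features = n_features, seed = seed)
    sp <- split_dataset(d, n_train, seed = seed + 1)
    std <- standardize(sp$train, list(sp$valid))
    out <- list(train = std$train, valid = std$others[[1]],
                relevant = d$relevant)
    cache[[key]] <- out
    out
  }
})
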