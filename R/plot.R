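#' Plot an experiment summary
#'
#' Draws the mean of one criterion against p for each training-set size,
#' with whiskers of two standard deviations around each mean.
#'
#' @param x An `irwp_experiment` from [run_experiment()].
#' @param metric One of `"feature_selection_error"`, `"prediction_error"`,
#'   `"n_selected"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @importFrom graphics arrows axis legend matplot
#' @export
plot.irwp_experiment <- function(x, metric = "feature_selection_error", ...) {
  s <- x$summary[x$summary$metric == metric, ]
  if (nrow(s) == 0L) stop("unknown metric '", metric, "'", call. = FALSE)
  sizes <- sort(unique(s$n_train))
  ps <- sort(unique(s$p))
  mu <- sapply(sizes, function(k) {
    sub <- s[s$n_train == k, ]
    sub$mean[match(ps, sub$p)]
  })
  dev <- sapply(sizes, function(k) {
    sub <- s[s$n_train == k, ]
    sub$sd[match(ps, sub$p)]
  })
  mu <- matrix(mu, nrow = length(ps))
  dev <- matrix(dev, nrow = length(ps))
  ylim <- range(mu - 2 * dev, mu + 2 * dev, 0, finite = TRUE)
  matplot(ps, mu, type = "b", pch = 19, lty = 1, xlab = "p",
          ylab = paste0(gsub("_", " ", metric),
                        if (metric != "n_selected") " (%)" else ""),
          ylim = ylim, ...)
  for (j in seq_along(sizes)) {
    keep <- dev[, j] > 0
    if (any(keep)) {
      arrows(ps[keep], mu[keep, j] - 2 * dev[keep, j],
             ps[keep], mu[keep, j] + 2 * dev[keep, j],
             angle = 90, code = 3, length = 0.03, col = j)
    }
  }
  legend("topright", legend = paste0("train = ", sizes), col = seq_along(sizes),
         pch = 19, lty = 1, bty = "n")
  invisible(x)
}
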