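#' Construct a labeled dataset
#'
#' Bundles a numeric sample-by-feature matrix with binary labels in
#' \{-1, +1\} and, for synthetic data, the indices of the ground-truth
#' relevant features.
#'
#' @param features Numeric matrix, samples in rows, features in columns.
#'   All entries must be finite.
#' @param labels Vector of length `nrow(features)` with entries -1 or +1.
#' @param relevant Optional integer vector of ground-truth relevant feature
#'   indices (subset of `1:ncol(features)`); synthetic data only.
#' @return An object of class `lp_dataset`: a list with elements `x`
#'   (matrix), `y` (numeric vector of -1/+1) and `relevant` (integer vector
#'   or `NULL`).
#' @export
#' @examples
#' d <- lp_dataset(matrix(rnorm(20), 10, 2), rep(c(-1, 1), 5))
#' d
lp_dataset <- function(features, labels, relevant = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (!all(is.finite(features))) {
    stop("'features' contains non-finite entries", call. = FALSE)
  }
  labels <- as.numeric(labels)
  if (length(labels) != nrow(features)) {
    stop("length(labels) must equal nrow(features)", call. = FALSE)
  }
  if (!all(labels %in% c(-1, 1))) {
    stop("labels must all be -1 or +1", call. = FALSE)
  }
  if (!is.null(relevant)) {
    relevant <- sort(unique(as.integer(relevant)))
    if (any(relevant < 1L) || any(relevant > ncol(features))) {
      stop("'relevant' indices out of range", call. = FALSE)
    }
  }
  structure(list(x = features, y = labels, relevant = relevant),
            class = "lp_dataset")
}

#' @export
print.lp_dataset <- function(x, ...) {
  cat(sprintf("<lp_dataset> %d samples x %d features (%d labeled +1, %d labeled -1)\n",
              nrow(x$x), ncol(x$x), sum(x$y > 0), sum(x$y < 0)))
  if (!is.null(x$relevant)) {
    cat("  relevant features:", paste(x$relevant, collapse = ", "), "\n")
  }
  invisible(x)
}

# coerce fit inputs: either an lp_dataset or (matrix, labels)
as_xy <- function(x, y) {
  if (inherits(x, "lp_dataset")) {
    list(x = x$x, y = x$y)
  } else {
    d <- lp_dataset(x, y)
    list(x = d$x, y = d$y)
  }
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L) {
    stop_irwp("training data contain a single class; both -1 and +1 are required",
              class = "irwp_data_error")
  }
  invisible(TRUE)
}

#' Read a delimited dataset
#'
#' Reads a CSV (or, by file extension, TSV) file of samples in rows. Labels
#' are taken from the column named `label_col` (default `"label"`), or from
#' a separate single-column file. Numeric -1/+1 labels are used as-is; any
#' other two-level labels are mapped in first-seen order to +1 then -1, and
#' the mapping is recorded in the `label_map` attribute.
#'
#' @param path Path to the feature file (`.csv` comma-separated, `.tsv`/
#'   `.txt` tab-separated; header row required).
#' @param label_col Name of the label column inside `path`. Ignored when
#'   `labels_path` is given.
#' @param labels_path Optional path to a one-column label file.
#' @return An [lp_dataset()] with a `label_map` attribute (named vector
#'   mapping original level -> -1/+1) when labels were recoded.
#' @export
read_dataset <- function(path, label_col = "label", labels_path = NULL) {
  if (!file.exists(path)) {
    stop_irwp(sprintf("cannot read '%s': no such file", path),
              class = "irwp_io_error")
  }
  df <- read_delim_auto(path)
  if (is.null(labels_path)) {
    if (!label_col %in% names(df)) {
      stop_irwp(sprintf("label column '%s' not found in '%s'", label_col, path),
                class = "irwp_data_error")
    }
    raw <- df[[label_col]]
    df[[label_col]] <- NULL
  } else {
    if (!file.exists(labels_path)) {
      stop_irwp(sprintf("cannot read '%s': no such file", labels_path),
                class = "irwp_io_error")
    }
    ldf <- read_delim_auto(labels_path)
    if (ncol(ldf) != 1L) {
      stop_irwp("label file must contain exactly one column",
                class = "irwp_data_error")
    }
    raw <- ldf[[1L]]
  }
  enc <- encode_labels(raw)
  x <- as.matrix(df)
  if (!is.numeric(x)) {
    stop_irwp("feature columns must all be numeric", class = "irwp_data_error")
  }
  out <- lp_dataset(x, enc$y)
  attr(out, "label_map") <- enc$map
  out
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE)
}

# first-seen level -> +1, second -> -1; -1/+1 numerics pass through
encode_labels <- function(raw) {
  if (is.numeric(raw) && all(raw %in% c(-1, 1))) {
    return(list(y = as.numeric(raw), map = NULL))
  }
  lev <- unique(as.character(raw))
  if (length(lev) != 2L) {
    stop_irwp(sprintf("labels must have exactly two levels, found %d",
                      length(lev)), class = "irwp_data_error")
  }
  map <- c(1, -1)
  names(map) <- lev
  list(y = unname(map[as.character(raw)]), map = map)
}

#' Write a dataset as CSV
#'
#' Writes samples as rows with feature columns `f001...` and a final
#' `label` column, the format [read_dataset()] reads back.
#'
#' @param data An [lp_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "lp_dataset"))
  n <- ncol(data$x)
  cn <- colnames(data$x)
  if (is.null(cn)) cn <- sprintf("f%0*d", max(3L, nchar(n)), seq_len(n))
  df <- as.data.frame(data$x)
  names(df) <- cn
  df$label <- data$y
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
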