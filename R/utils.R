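# Input validation shared by trainers, decomposition and the HOTS pipeline.

#' Coerce a feature table to a numeric matrix
#'
#' Accepts a numeric matrix or a data frame of numeric columns. Missing values
#' are rejected: the decomposition walks concrete decision paths, which are
#' undefined for missing inputs.
#'
#' @param X matrix or data.frame, one sample per row.
#' @return numeric matrix with column names (generated as `f1`, `f2`, ... when
#'   absent).
#' @keywords internal
as_feature_matrix <- function(X) {
  if (is.data.frame(X)) {
    bad <- !vapply(X, is.numeric, logical(1))
    if (any(bad)) {
      stop("non-numeric feature column(s): ", paste(names(X)[bad], collapse = ", "))
    }
    X <- as.matrix(X)
  }
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("X must be a numeric matrix or a data frame of numeric columns")
  }
  if (anyNA(X)) stop("missing values in feature table are not supported")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

# Nearest single-precision value, as a double. External boosted-model dumps
# store thresholds in float32 and compare in float32; reproducing their
# routing exactly requires doing the same.
float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L),
          what = "double", n = length(x), size = 4L)
}

check_labels <- function(y, n, require_both_classes = TRUE) {
  if (is.factor(y)) y <- as.integer(as.character(y))
  if (is.logical(y)) y <- as.integer(y)
  if (!is.numeric(y)) stop("labels must be numeric 0/1")
  if (anyNA(y)) stop("missing values in labels")
  if (!all(y %in% c(0, 1))) stop("labels must be coded 0/1")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (require_both_classes && length(unique(y)) < 2L) stop("degenerate labels: only one class present")
  as.integer(y)
}

check_feature_vector <- function(x, n_features) {
  x <- as.numeric(x)
  if (length(x) != n_features) {
    stop("dimension error: expected ", n_features, " features, got ", length(x))
  }
  if (anyNA(x)) stop("missing values in feature vector are not supported")
  x
}

#' Read a feature table from CSV
#'
#' Header row carries the feature names; all cells must be numeric.
#'
#' @param path path to a CSV file, UTF-8, `.` decimal.
#' @return numeric matrix.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  as_feature_matrix(df)
}

#' Read a 0/1 label vector from CSV
#'
#' A single column (with or without a header) of 0/1 values.
#'
#' @param path path to a CSV file.
#' @return integer vector of 0/1.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- utils::read.csv(path, header = FALSE, nrows = 1)
  has_header <- !is.numeric(first[[1]])
  df <- utils::read.csv(path, header = has_header)
  y <- df[[1]]
  check_labels(y, length(y), require_both_classes = FALSE)
}
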