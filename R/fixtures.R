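# Self-contained inputs: the printed worked-example tree, a bundled binary
# iris table, and a seeded synthetic generator with planted, directionally
# known feature effects.

#' The worked-example tree and its probe sample
#'
#' A depth-4 probability-space tree over three features (sepal length, sepal
#' width, petal length) whose decision path for the probe sample
#' `(sepal_length = 6.9, sepal_width = 3.1, petal_length = 4.9)` carries node
#' values 0.493 (root), 0.051, 0.25, 0.143 and leaf 1.0, splitting on petal
#' length twice, then sepal width, then sepal length. Decomposing the probe
#' therefore yields contributions petal length -0.243, sepal width -0.107,
#' sepal length +0.857 around bias 0.493, summing to probability 1.0. Only
#' the path is prescribed; each off-path child is a leaf with its parent's
#' value (zero contribution on those branches), and thresholds are fixed
#' values that route the probe as stated.
#'
#' @return list with `tree` (a `tree_model`) and `probe` (named feature
#'   vector).
#' @examples
#' wx <- worked_example_tree()
#' decompose(wx$tree, wx$probe)
#' @export
worked_example_tree <- function() {
  feats <- c("sepal_length", "sepal_width", "petal_length")
  nd <- function(id, feature, threshold, left, right, value, n) {
    data.frame(id = id, feature = feature, threshold = threshold,
               left = left, right = right, value = value, n = n,
               impurity = gini_binary(value), gain = NA_real_)
  }
  leaf <- function(id, value, n) nd(id, NA_integer_, NA_real_, NA_integer_, NA_integer_, value, n)
  nodes <- rbind(
    nd(1L, 3L, 5.00, 2L, 3L, 0.493, 100L),   # petal_length <= 5.00 -> left
    nd(2L, 3L, 4.95, 4L, 5L, 0.051, 60L),    # petal_length <= 4.95 -> left
    leaf(3L, 0.493, 40L),
    nd(4L, 2L, 3.15, 6L, 7L, 0.250, 20L),    # sepal_width <= 3.15 -> left
    leaf(5L, 0.051, 40L),
    nd(6L, 1L, 6.00, 8L, 9L, 0.143, 8L),     # sepal_length > 6.00 -> right
    leaf(7L, 0.250, 12L),
    leaf(8L, 0.143, 3L),
    leaf(9L, 1.000, 5L))
  tree <- tree_model(nodes, feats, value_space = "probability")
  probe <- c(sepal_length = 6.9, sepal_width = 3.1, petal_length = 4.9)
  list(tree = tree, probe = probe)
}

#' Generate synthetic binary-class data with planted effects
#'
#' Labels are Bernoulli draws at `class_balance`; every feature is Gaussian
#' noise with standard deviation `noise_sd`, and each informative feature's
#' class-1 mean is shifted by `mean_shift * noise_sd` relative to its class-0
#' mean (positive shift = larger values in the positive class). Identical
#' arguments and seed reproduce the data exactly.
#'
#' @param n_samples number of samples.
#' @param n_features number of features (named `f1`, `f2`, ...).
#' @param informative indices of the informative features.
#' @param mean_shift class-1 minus class-0 mean, in units of `noise_sd`;
#'   recycled along `informative`.
#' @param noise_sd noise standard deviation (> 0).
#' @param class_balance probability of the positive class, in (0, 1).
#' @param seed integer seed.
#' @return list with `X` (matrix) and `y` (integer 0/1).
#' @export
make_synthetic <- function(n_samples = 500L, n_features = 5L,
                           informative = 1L, mean_shift = 3,
                           noise_sd = 1, class_balance = 0.5, seed = 1L) {
  stopifnot(n_samples >= 2, n_features >= 1, noise_sd > 0,
            class_balance > 0, class_balance < 1)
  informative <- as.integer(informative)
  if (anyDuplicated(informative) ||
      any(informative < 1 | informative > n_features)) {
    stop("informative indices must be unique and within 1..n_features")
  }
  mean_shift <- rep_len(as.numeric(mean_shift), length(informative))
  set.seed(seed)
  y <- stats::rbinom(n_samples, 1L, class_balance)
  X <- matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
              n_samples, n_features,
              dimnames = list(NULL, paste0("f", seq_len(n_features))))
  for (i in seq_along(informative)) {
    X[y == 1L, informative[i]] <- X[y == 1L, informative[i]] +
      mean_shift[i] * noise_sd
  }
  list(X = X, y = as.integer(y))
}

#' The bundled two-class iris table
#'
#' The canonical 100-sample iris subset with setosa removed: versicolor is
#' the negative class (0) and virginica the positive class (1), with the four
#' flower-dimension features.
#'
#' @return list with `X` (100 x 4 matrix: `sepal_length`, `sepal_width`,
#'   `petal_length`, `petal_width`) and `y` (integer 0/1, 50 of each).
#' @export
iris_binary <- function() {
  path <- system.file("extdata", "iris_binary.csv", package = "hollowtree")
  if (path == "" || !file.exists(path)) stop("bundled iris fixture is missing")
  df <- utils::read.csv(path)
  y <- check_labels(df$class, nrow(df), FALSE)
  X <- as_feature_matrix(df[setdiff(names(df), "class")])
  list(X = X, y = y)
}
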