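# Independent oracles and small data builders shared across the suite.
# The oracles deliberately avoid the package's vectorized code paths: they
# walk trees node by node with plain loops.

# Naive per-sample path walk: returns per-feature contribution vector and the
# reached leaf value, summing (child value - parent value) on the path.
oracle_decompose <- function(tree, x) {
  nd <- tree$nodes
  contrib <- stats::setNames(numeric(tree$n_features), tree$feature_names)
  at <- tree$root_id
  repeat {
    r <- which(nd$id == at)
    if (is.na(nd$feature[r])) {
      return(list(contributions = contrib, leaf_value = nd$value[r]))
    }
    f <- nd$feature[r]
    go_left <- if (tree$split_rule == "le") x[f] <= nd$threshold[r] else x[f] < nd$threshold[r]
    child <- if (go_left) nd$left[r] else nd$right[r]
    contrib[f] <- contrib[f] + nd$value[which(nd$id == child)] - nd$value[r]
    at <- child
  }
}

# Exhaustive enumeration of every (feature, midpoint) split candidate by Gini
# gain; returns the best with lowest-feature / lowest-threshold tie-breaks.
oracle_best_split <- function(X, y) {
  gini <- function(v) {
    if (!length(v)) return(0)
    p <- mean(v)
    2 * p * (1 - p)
  }
  n <- nrow(X)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) next
    for (i in seq_len(length(u) - 1)) {
      thr <- (u[i] + u[i + 1]) / 2
      l <- X[, j] <= thr
      gain <- n * gini(y) - sum(l) * gini(y[l]) - sum(!l) * gini(y[!l])
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = j, threshold = thr, gain = gain)
      }
    }
  }
  best
}

# AUC by brute-force pair counting, ties worth one half.
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Random training data with a weak planted signal; used to grow assorted
# trees/ensembles for property tests.
random_problem <- function(n = 60, p = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.integer(X[, 1] + rnorm(n) > 0)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}

# One representative input per leaf of a trained tree, found by routing the
# training rows: trained leaves always hold at least one row.
one_row_per_leaf <- function(tree, X) {
  leaf <- predict(tree, X, type = "leaf")
  X[match(unique(leaf), leaf), , drop = FALSE]
}

# Hand-built decomposition sets for exercising the filtering / aggregation
# steps without a trained model.
fake_decomposition <- function(contributions, probability, true_class = NULL,
                               space = "log_odds") {
  contributions <- as.matrix(contributions)
  colnames(contributions) <- paste0("f", seq_len(ncol(contributions)))
  structure(
    list(contributions = contributions, bias = 0, probability = probability,
         raw_output = if (space == "log_odds") stats::qlogis(probability) else probability,
         predicted_class = as.integer(probability >= 0.5),
         true_class = true_class, space = space,
         feature_names = colnames(contributions),
         sample_id = as.character(seq_len(nrow(contributions))),
         oriented = FALSE),
    class = "decomposition")
}

expect_conservation <- function(d, tol = 1e-9) {
  expect_lt(max(abs(d$bias + rowSums(d$contributions) - d$raw_output)), tol)
}
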