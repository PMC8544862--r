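# Additive path decomposition of tree predictions.
#
# A prediction is expressed as bias + sum over features of that feature's
# contribution, where the bias is the expected model output at the root and
# each split on the path contributes (child value - parent value) to the
# feature it tests. For a single probability-space tree the pieces sum to the
# predicted class-1 probability; for a boosted ensemble the per-tree pieces
# are summed in log-odds space and the bias is the base score plus the
# per-tree root expectations.

#' Trace the decision path of one sample through a tree
#'
#' Walks the root-to-leaf path taken by `x` and records, for every split on
#' the way, the local increment of the feature tested there: the child's
#' expected value minus the parent's. The increments telescope, so they sum
#' to leaf value minus root value.
#'
#' @param tree a `tree_model`.
#' @param x a single feature vector.
#' @return data.frame with one row per split taken, columns `node_id`,
#'   `feature` (index), `feature_name`, `delta`.
#' @export
trace_path <- function(tree, x) {
  validate_tree_model(tree)
  x <- check_feature_vector(x, tree$n_features)
  nd <- tree$nodes
  idx <- match(seq_len(max(nd$id)), nd$id)
  at <- tree$root_id
  steps <- list()
  repeat {
    r <- idx[at]
    if (is.na(nd$feature[r])) break
    f <- nd$feature[r]
    xv <- if (tree$precision == "single") float32(x[f]) else x[f]
    go_left <- if (tree$split_rule == "le") xv <= nd$threshold[r] else xv < nd$threshold[r]
    child <- if (go_left) nd$left[r] else nd$right[r]
    steps[[length(steps) + 1L]] <- data.frame(
      node_id = at, feature = f, feature_name = tree$feature_names[f],
      delta = nd$value[idx[child]] - nd$value[r])
    at <- child
  }
  if (!length(steps)) {
    return(data.frame(node_id = integer(), feature = integer(),
                      feature_name = character(), delta = numeric()))
  }
  do.call(rbind, steps)
}

# Per-feature contribution matrix for all rows of X through one tree, plus the
# reached leaf values. Rows are pushed down the tree level by level; moving a
# set of rows from a node to a child adds (child value - node value) to those
# rows' entry for the split feature. O(#nodes * rows) instead of a per-row walk.
tree_contributions <- function(tree, X) {
  nd <- tree$nodes
  idx <- match(seq_len(max(nd$id)), nd$id)
  n <- nrow(X)
  contrib <- matrix(0, n, tree$n_features,
                    dimnames = list(NULL, tree$feature_names))
  leaf_value <- numeric(n)
  frontier <- list(list(id = tree$root_id, rows = seq_len(n)))
  while (length(frontier)) {
    cur <- frontier[[length(frontier)]]
    frontier[[length(frontier)]] <- NULL
    r <- idx[cur$id]
    if (is.na(nd$feature[r])) {
      leaf_value[cur$rows] <- nd$value[r]
      next
    }
    f <- nd$feature[r]
    xv <- X[cur$rows, f]
    if (tree$precision == "single") xv <- float32(xv)
    go_left <- if (tree$split_rule == "le") xv <= nd$threshold[r] else xv < nd$threshold[r]
    for (side in c("left", "right")) {
      rows <- cur$rows[if (side == "left") go_left else !go_left]
      if (!length(rows)) next
      child <- nd[[side]][r]
      contrib[rows, f] <- contrib[rows, f] + nd$value[idx[child]] - nd$value[r]
      frontier[[length(frontier) + 1L]] <- list(id = child, rows = rows)
    }
  }
  list(contributions = contrib, leaf_value = leaf_value)
}

new_decomposition <- function(contributions, bias, probability, raw_output,
                              predicted_class, true_class, space, feature_names,
                              sample_id, oriented = FALSE) {
  structure(
    list(contributions = contributions, bias = bias, probability = probability,
         raw_output = raw_output, predicted_class = predicted_class,
         true_class = true_class, space = space, feature_names = feature_names,
         sample_id = sample_id, oriented = oriented),
    class = "decomposition")
}

#' Decompose predictions into per-feature contributions
#'
#' Expresses each prediction as `bias + sum(contributions)`:
#' for a single probability-space tree the bias is the root's class-1
#' fraction and the pieces sum to the predicted probability; for a boosted
#' ensemble the contributions are summed across trees in log-odds space and
#' the bias is the base score plus the per-tree root expectations, the pieces
#' summing to the total margin. Contributions from repeated splits on the
#' same feature along a path accumulate on that feature.
#'
#' @param model a `tree_model` or `boosted_trees` object.
#' @param newdata feature matrix/data frame, or a single feature vector.
#' @param y optional true 0/1 labels, carried along for downstream filtering.
#' @param ... unused.
#' @return object of class `decomposition`: contribution matrix (samples x
#'   features), scalar `bias`, per-sample `probability`, `raw_output` (the
#'   probability for trees, the margin for ensembles), `predicted_class`,
#'   optional `true_class`, and `space` (`"probability"` or `"log_odds"`).
#' @examples
#' wx <- worked_example_tree()
#' decompose(wx$tree, wx$probe)
#' @export
decompose <- function(model, newdata, y = NULL, ...) UseMethod("decompose")

#' @rdname decompose
#' @export
decompose.tree_model <- function(model, newdata, y = NULL, ...) {
  validate_tree_model(model)
  newdata <- as_newdata_matrix(newdata, model$n_features)
  tc <- tree_contributions(model, newdata)
  bias <- model$nodes$value[match(model$root_id, model$nodes$id)]
  raw <- tc$leaf_value
  if (model$value_space == "probability") {
    prob <- raw
    space <- "probability"
  } else {
    prob <- stats::plogis(raw)
    space <- "log_odds"
  }
  true_class <- if (!is.null(y)) check_labels(y, nrow(newdata), FALSE)
  new_decomposition(tc$contributions, bias, prob, raw,
                    as.integer(prob >= 0.5), true_class, space,
                    model$feature_names, default_sample_id(newdata))
}

#' @rdname decompose
#' @export
decompose.boosted_trees <- function(model, newdata, y = NULL, ...) {
  newdata <- as_newdata_matrix(newdata, model$n_features)
  contrib <- matrix(0, nrow(newdata), model$n_features,
                    dimnames = list(NULL, model$feature_names))
  bias <- model$base_score
  margin <- rep(model$base_score, nrow(newdata))
  for (tr in model$trees) {
    tc <- tree_contributions(tr, newdata)
    contrib <- contrib + tc$contributions
    bias <- bias + tr$nodes$value[match(tr$root_id, tr$nodes$id)]
    margin <- margin + tc$leaf_value
  }
  prob <- stats::plogis(margin)
  true_class <- if (!is.null(y)) check_labels(y, nrow(newdata), FALSE)
  new_decomposition(contrib, bias, prob, margin,
                    as.integer(prob >= 0.5), true_class, "log_odds",
                    model$feature_names, default_sample_id(newdata))
}

default_sample_id <- function(X) {
  if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(nrow(X)))
}

#' Orient log-odds contributions toward the predicted class
#'
#' Boosted-tree contributions are log odds of the positive class. For samples
#' predicted negative, the log odds of the predicted (negative) class are the
#' negated positive-class log odds, so those rows are sign-flipped; rows
#' predicted positive are unchanged. Applying the operation twice restores
#' the original decomposition.
#'
#' @param d a `decomposition` in log-odds space.
#' @return the decomposition with contributions oriented to each sample's
#'   predicted class (`oriented = TRUE` flag set).
#' @export
orient_to_predicted_class <- function(d) {
  stopifnot(inherits(d, "decomposition"))
  if (d$space != "log_odds") stop("orientation defined for log-odds only")
  flip <- d$predicted_class == 0L
  d$contributions[flip, ] <- -d$contributions[flip, , drop = FALSE]
  d$oriented <- !d$oriented
  d
}

# Subset a decomposition to the samples in `keep` (logical or integer).
subset_decomposition <- function(d, keep) {
  d$contributions <- d$contributions[keep, , drop = FALSE]
  for (fld in c("probability", "raw_output", "predicted_class", "sample_id")) {
    d[[fld]] <- d[[fld]][keep]
  }
  if (!is.null(d$true_class)) d$true_class <- d$true_class[keep]
  d
}

n_samples <- function(d) nrow(d$contributions)

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("Decomposition of %d prediction(s) in %s space (bias %.4g%s)\n",
              n_samples(x), x$space, x$bias,
              if (x$oriented) ", oriented to predicted class" else ""))
  k <- min(n_samples(x), 5L)
  if (k > 0) {
    df <- data.frame(probability = round(x$probability[seq_len(k)], 4),
                     predicted_class = x$predicted_class[seq_len(k)],
                     round(x$contributions[seq_len(k), , drop = FALSE], 4),
                     check.names = FALSE)
    print(df)
    if (n_samples(x) > k) cat("... (", n_samples(x) - k, " more)\n", sep = "")
  }
  invisible(x)
}

#' Write per-sample explanations as JSON lines
#'
#' Emits one JSON object per sample with fields `sample_id`, `bias`,
#' `probability`, `predicted_class` and `contributions` (name/value map), in
#' that order, suitable for line-oriented diffing.
#'
#' @param d a `decomposition`.
#' @param path output file; `""` writes to stdout.
#' @return invisibly, the vector of JSON lines.
#' @export
write_explanations <- function(d, path = "") {
  stopifnot(inherits(d, "decomposition"))
  lines <- vapply(seq_len(n_samples(d)), function(i) {
    jsonlite::toJSON(list(
      sample_id = d$sample_id[i],
      bias = d$bias,
      probability = d$probability[i],
      predicted_class = d$predicted_class[i],
      contributions = as.list(d$contributions[i, ])),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
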