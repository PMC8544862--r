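# Binary decision trees: structure, a deterministic CART trainer, prediction.
#
# A tree is stored as a node table (one row per node) rather than nested
# lists: columns id, feature (split feature index, NA at leaves), threshold,
# left, right (child ids, NA at leaves), value (expected model output at the
# node), n (cover: training samples routed through the node), impurity (Gini,
# probability-space trees only) and gain (split quality). Routing convention:
# x[feature] <= threshold goes left ("le"); imported models may instead use
# the strict "lt" convention.

node_columns <- c("id", "feature", "threshold", "left", "right",
                  "value", "n", "impurity", "gain")

#' Construct a tree model object
#'
#' Low-level constructor used by the trainers, the model-dump importer and the
#' fixtures. Most users will call [cart_tree()] or [boosted_trees()] instead.
#'
#' @param nodes data.frame with columns `id`, `feature`, `threshold`, `left`,
#'   `right`, `value`, `n`, `impurity`, `gain`; leaves have `NA` in
#'   `feature`/`threshold`/`left`/`right`.
#' @param feature_names character vector naming the model's input features.
#' @param value_space `"probability"` (node value is the class-1 fraction) or
#'   `"margin"` (node value is a log-odds increment).
#' @param split_rule `"le"` (`x <= threshold` goes left) or `"lt"`
#'   (`x < threshold` goes left).
#' @param precision `"double"`, or `"single"` for models whose comparisons
#'   are performed in float32 (externally trained boosters); feature values
#'   are then rounded to single precision before each comparison.
#' @param root_id id of the root node.
#' @return object of class `tree_model`.
#' @export
tree_model <- function(nodes, feature_names,
                       value_space = c("probability", "margin"),
                       split_rule = c("le", "lt"), root_id = 1L,
                       precision = c("double", "single")) {
  value_space <- match.arg(value_space)
  split_rule <- match.arg(split_rule)
  precision <- match.arg(precision)
  stopifnot(is.data.frame(nodes), all(node_columns %in% names(nodes)))
  obj <- structure(
    list(nodes = nodes[node_columns], root_id = as.integer(root_id),
         n_features = length(feature_names),
         feature_names = as.character(feature_names),
         value_space = value_space, split_rule = split_rule,
         precision = precision),
    class = "tree_model")
  validate_tree_model(obj)
  obj
}

#' Check the structural invariants of a tree model
#'
#' Verifies that the nodes form a single rooted binary tree: ids unique, all
#' nodes reachable from the root exactly once, every node either a leaf or a
#' full split with in-range feature indices, and (for probability-space trees)
#' node values in \eqn{[0, 1]}.
#'
#' @param model a `tree_model`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_tree_model <- function(model) {
  nd <- model$nodes
  if (anyDuplicated(nd$id)) stop("malformed tree: duplicated node ids")
  if (!model$root_id %in% nd$id) stop("malformed tree: root id not present")
  is_leaf <- is.na(nd$feature)
  full_split <- !is.na(nd$feature) & !is.na(nd$threshold) &
    !is.na(nd$left) & !is.na(nd$right)
  if (!all(is_leaf | full_split)) {
    stop("malformed tree: a node must be a leaf or carry feature, threshold and both children")
  }
  if (any(nd$feature[!is_leaf] < 1 | nd$feature[!is_leaf] > model$n_features)) {
    stop("malformed tree: split feature index out of range")
  }
  kids <- c(nd$left[!is_leaf], nd$right[!is_leaf])
  if (!all(kids %in% nd$id)) stop("malformed tree: child id not present")
  if (anyDuplicated(kids) || model$root_id %in% kids) {
    stop("malformed tree: a node has more than one parent or the root has a parent")
  }
  # reachability: parent links cover every non-root node exactly once, and no
  # cycles because each node has a single parent and the root has none
  if (length(kids) != nrow(nd) - 1L) stop("malformed tree: unreachable nodes")
  if (model$value_space == "probability" &&
      any(nd$value < -1e-12 | nd$value > 1 + 1e-12)) {
    stop("malformed tree: probability-space node value outside [0, 1]")
  }
  if (any(nd$n < 0)) stop("malformed tree: negative cover")
  invisible(model)
}

is_leaf_node <- function(nodes, id) is.na(nodes$feature[match(id, nodes$id)])

gini_binary <- function(p) 2 * p * (1 - p)

# Best split of `y01` (0/1) over the columns of X restricted to `rows`, by
# exact greedy Gini reduction over midpoints between consecutive distinct
# values. Returns NULL when no split has positive gain. Ties broken by lowest
# feature index then lowest threshold (features and thresholds are scanned in
# ascending order and only strictly better gains replace the incumbent).
best_gini_split <- function(X, y01, rows, min_samples_split) {
  n <- length(rows)
  if (n < min_samples_split) return(NULL)
  y <- y01[rows]
  parent_imp <- gini_binary(mean(y))
  if (parent_imp == 0) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xj <- X[rows, j]
    ord <- order(xj)
    xs <- xj[ord]
    ys <- y[ord]
    cut_at <- which(xs[-n] < xs[-1])      # split after these sorted positions
    if (!length(cut_at)) next
    c1 <- cumsum(ys)
    nl <- cut_at
    nr <- n - nl
    p_l <- c1[cut_at] / nl
    p_r <- (c1[n] - c1[cut_at]) / nr
    weighted <- nl * gini_binary(p_l) + nr * gini_binary(p_r)
    gain <- n * parent_imp - weighted
    k <- which.max(gain)                  # first max: lowest threshold wins ties
    if (gain[k] > 1e-12 && (is.null(best) || gain[k] > best$gain + 1e-12)) {
      thr <- (xs[cut_at[k]] + xs[cut_at[k] + 1]) / 2
      best <- list(feature = j, threshold = thr, gain = gain[k],
                   left_rows = rows[xj <= thr], right_rows = rows[xj > thr])
    }
  }
  best
}

#' Fit a binary classification tree by exact greedy CART
#'
#' Grows a depth-limited binary tree for 0/1 labels. Each node's value is the
#' fraction of class-1 training samples routed to it, its impurity is the
#' binary Gini index \eqn{2p(1-p)}, and splits minimize the weighted child
#' Gini over every midpoint between consecutive distinct feature values. The
#' procedure is fully deterministic: ties in gain are resolved toward the
#' lowest feature index, then the lowest threshold.
#'
#' @param X numeric feature matrix or data frame, one sample per row.
#' @param y 0/1 labels, both classes present.
#' @param max_depth maximum number of split levels (>= 1).
#' @param min_samples_split smallest node size eligible for splitting (>= 2).
#' @return a `tree_model` with `value_space = "probability"`.
#' @examples
#' fit <- cart_tree(cbind(x = c(0, 0, 1, 1)), c(0, 0, 1, 1), max_depth = 1)
#' predict(fit, cbind(x = c(0, 1)))
#' @export
cart_tree <- function(X, y, max_depth = 4L, min_samples_split = 2L) {
  X <- as_feature_matrix(X)
  y <- check_labels(y, nrow(X))
  stopifnot(max_depth >= 1, min_samples_split >= 2)

  rows_list <- list()
  nodes <- list()
  next_id <- 0L
  new_id <- function() {
    next_id <<- next_id + 1L
    next_id
  }
  grow <- function(rows, depth) {
    id <- new_id()
    p <- mean(y[rows])
    node <- data.frame(id = id, feature = NA_integer_, threshold = NA_real_,
                       left = NA_integer_, right = NA_integer_,
                       value = p, n = length(rows),
                       impurity = gini_binary(p), gain = NA_real_)
    if (depth < max_depth) {
      sp <- best_gini_split(X, y, rows, min_samples_split)
      if (!is.null(sp)) {
        node$feature <- sp$feature
        node$threshold <- sp$threshold
        node$gain <- sp$gain
        nodes[[id]] <<- node                      # reserve slot before recursion
        left_id <- grow(sp$left_rows, depth + 1L)
        right_id <- grow(sp$right_rows, depth + 1L)
        nodes[[id]]$left <<- left_id
        nodes[[id]]$right <<- right_id
        return(id)
      }
    }
    nodes[[id]] <<- node
    id
  }
  grow(seq_len(nrow(X)), 0L)
  tree_model(do.call(rbind, nodes), colnames(X), value_space = "probability")
}

# Vectorized routing: returns for each row of X the id of the leaf it reaches.
route_to_leaf <- function(model, X) {
  nd <- model$nodes
  idx <- match(seq_len(max(nd$id)), nd$id)    # id -> row lookup
  at <- rep(model$root_id, nrow(X))
  repeat {
    r <- idx[at]
    open <- !is.na(nd$feature[r])
    if (!any(open)) return(at)
    io <- which(open)
    ro <- r[io]
    xv <- X[cbind(io, nd$feature[ro])]
    if (model$precision == "single") xv <- float32(xv)
    go_left <- if (model$split_rule == "le") xv <= nd$threshold[ro] else xv < nd$threshold[ro]
    at[io] <- ifelse(go_left, nd$left[ro], nd$right[ro])
  }
}

#' Predict from a single tree
#'
#' @param object a `tree_model`.
#' @param newdata feature matrix/data frame, or a single feature vector.
#' @param type `"value"` for the reached leaf's value (a probability for
#'   probability-space trees, a margin increment otherwise), `"class"` for the
#'   0/1 label at the 0.5 probability threshold (probability-space trees
#'   only), or `"leaf"` for the reached leaf's node id.
#' @param ... unused.
#' @return numeric (or integer) vector, one element per row of `newdata`.
#' @export
predict.tree_model <- function(object, newdata,
                               type = c("value", "class", "leaf"), ...) {
  type <- match.arg(type)
  newdata <- as_newdata_matrix(newdata, object$n_features)
  leaf <- route_to_leaf(object, newdata)
  if (type == "leaf") return(leaf)
  val <- object$nodes$value[match(leaf, object$nodes$id)]
  if (type == "value") return(val)
  if (object$value_space != "probability") {
    stop("class predictions are defined for probability-space trees only")
  }
  as.integer(val >= 0.5)
}

as_newdata_matrix <- function(newdata, n_features) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(check_feature_vector(newdata, n_features), nrow = 1)
  } else {
    newdata <- as_feature_matrix(newdata)
    if (ncol(newdata) != n_features) {
      stop("dimension error: expected ", n_features, " features, got ", ncol(newdata))
    }
  }
  newdata
}

#' @export
print.tree_model <- function(x, ...) {
  n_leaves <- sum(is.na(x$nodes$feature))
  cat(sprintf("Binary decision tree (%s space): %d nodes (%d leaves), %d features\n",
              x$value_space, nrow(x$nodes), n_leaves, x$n_features))
  used <- sort(unique(x$nodes$feature[!is.na(x$nodes$feature)]))
  if (length(used)) {
    cat("split features:", paste(x$feature_names[used], collapse = ", "), "\n")
  }
  invisible(x)
}
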