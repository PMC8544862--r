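# Model persistence.
#
# Boosted ensembles use the widely shared JSON dump dialect: one nested
# object per tree with keys nodeid / split / split_condition / yes / no /
# children for internal nodes and nodeid / leaf for leaves, plus per-node
# statistics (cover, gain) when exported with statistics. In-package exports
# wrap the tree array in an object carrying base_score, feature_names and
# the routing rule; bare arrays (as produced by external boosters) are also
# accepted, in which case the strict-less-than routing convention of those
# tools is assumed and base_score/feature names may be supplied as arguments.
# Single trees use a flat mirrored schema (a node list).

#' Export a boosted ensemble as a JSON model dump
#'
#' @param model a `boosted_trees` fit.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_model_dump <- function(model, path) {
  stopifnot(inherits(model, "boosted_trees"))
  nest <- function(tr, id) {
    nd <- tr$nodes
    r <- match(id, nd$id)
    if (is.na(nd$feature[r])) {
      return(list(nodeid = id - 1L, leaf = nd$value[r], cover = nd$n[r]))
    }
    out <- list(nodeid = id - 1L,
                split = tr$feature_names[nd$feature[r]],
                split_condition = nd$threshold[r],
                yes = nd$left[r] - 1L, no = nd$right[r] - 1L,
                cover = nd$n[r],
                children = list(nest(tr, nd$left[r]), nest(tr, nd$right[r])))
    if (!is.na(nd$gain[r])) out$gain <- nd$gain[r]
    out
  }
  dump <- list(base_score = model$base_score,
               feature_names = model$feature_names,
               split_rule = model$trees[[1]]$split_rule,
               trees = lapply(model$trees, function(tr) nest(tr, tr$root_id)))
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

flatten_dump_tree <- function(obj, rows, feature_of) {
  id <- obj$nodeid + 1L
  if (!is.null(obj$leaf)) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, feature = NA_integer_, threshold = NA_real_,
      left = NA_integer_, right = NA_integer_, value = as.numeric(obj$leaf),
      n = if (!is.null(obj$cover)) as.numeric(obj$cover) else NA_real_,
      impurity = NA_real_, gain = NA_real_)
    return(rows)
  }
  if (is.null(obj$split) || is.null(obj$split_condition) ||
      is.null(obj$yes) || is.null(obj$no)) {
    stop("malformed model dump: internal node missing split/children keys")
  }
  rows[[length(rows) + 1L]] <- data.frame(
    id = id, feature = feature_of(obj$split),
    threshold = as.numeric(obj$split_condition),
    left = obj$yes + 1L, right = obj$no + 1L, value = NA_real_,
    n = if (!is.null(obj$cover)) as.numeric(obj$cover) else NA_real_,
    impurity = NA_real_,
    gain = if (!is.null(obj$gain)) as.numeric(obj$gain) else NA_real_)
  for (ch in obj$children) rows <- flatten_dump_tree(ch, rows, feature_of)
  rows
}

#' Import a boosted ensemble from a JSON model dump
#'
#' Reads either an in-package export (an object with `base_score`,
#' `feature_names`, `split_rule` and `trees`) or a bare array of per-tree
#' nested objects as written by common boosting libraries (routing: yes-branch
#' when `x < split_condition`). Internal node values, which the dump does not
#' carry, are reconstructed as the cover-weighted mean of each node's
#' descendant leaves; the dump must therefore include cover statistics.
#'
#' @param path path to the JSON dump.
#' @param feature_names feature names, required when the dump carries
#'   `f0`-style split indices without metadata; otherwise resolved from the
#'   dump.
#' @param base_score global log-odds offset when the dump has no metadata.
#' @return a `boosted_trees` model.
#' @export
import_model_dump <- function(path, feature_names = NULL, base_score = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(obj$trees)) {
    tree_objs <- obj$trees
    if (!is.null(obj$feature_names)) feature_names <- unlist(obj$feature_names)
    if (is.null(base_score)) base_score <- obj$base_score
    split_rule <- if (!is.null(obj$split_rule)) obj$split_rule else "lt"
    precision <- "double"
  } else {
    # bare array: the external dialect stores thresholds in float32 and
    # compares in float32, so routing must reproduce both
    tree_objs <- obj
    split_rule <- "lt"
    precision <- "single"
  }
  if (is.null(base_score)) base_score <- 0
  splits_seen <- character()
  collect <- function(o) {
    if (is.null(o$leaf)) {
      splits_seen <<- c(splits_seen, o$split)
      for (ch in o$children) collect(ch)
    }
  }
  for (t in tree_objs) collect(t)
  splits_seen <- unique(splits_seen)
  if (is.null(feature_names)) {
    if (length(splits_seen) && all(grepl("^f[0-9]+$", splits_seen))) {
      k <- max(as.integer(sub("^f", "", splits_seen))) + 1L
      feature_names <- paste0("f", seq_len(k) - 1L)
    } else if (!length(splits_seen)) {
      feature_names <- "f0"
    } else {
      stop("unknown feature name(s) in dump: supply feature_names")
    }
  }
  feature_of <- function(s) {
    i <- match(s, feature_names)
    if (is.na(i)) stop("unknown feature name in dump: ", s)
    i
  }
  trees <- lapply(tree_objs, function(t) {
    nodes <- do.call(rbind, flatten_dump_tree(t, list(), feature_of))
    internal <- !is.na(nodes$feature)
    if (any(internal)) {
      if (anyNA(nodes$n)) {
        stop("model dump lacks cover statistics; re-export with statistics")
      }
      nodes <- fill_internal_values(nodes)
    } else if (anyNA(nodes$n)) {
      nodes$n <- 0
    }
    if (precision == "single") nodes$threshold <- float32(nodes$threshold)
    tree_model(nodes, feature_names, value_space = "margin",
               split_rule = split_rule, root_id = nodes$id[1],
               precision = precision)
  })
  new_boosted_ensemble(trees, base_score, feature_names)
}

#' Export a single tree as JSON
#'
#' Flat mirrored schema: feature names, value space, routing rule and a node
#' list with id / feature / threshold / left / right / value / n_samples /
#' impurity.
#'
#' @param tree a `tree_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "tree_model"))
  nd <- tree$nodes
  nodes <- lapply(seq_len(nrow(nd)), function(r) {
    leaf <- is.na(nd$feature[r])
    list(id = nd$id[r],
         feature = if (leaf) NULL else tree$feature_names[nd$feature[r]],
         threshold = if (leaf) NULL else nd$threshold[r],
         left = if (leaf) NULL else nd$left[r],
         right = if (leaf) NULL else nd$right[r],
         value = nd$value[r], n_samples = nd$n[r],
         impurity = if (is.na(nd$impurity[r])) NULL else nd$impurity[r])
  })
  jsonlite::write_json(list(feature_names = tree$feature_names,
                            value_space = tree$value_space,
                            split_rule = tree$split_rule,
                            root_id = tree$root_id, nodes = nodes),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Import a single tree from JSON
#'
#' @param path path to a file written by [write_tree_json()].
#' @return a `tree_model`.
#' @export
read_tree_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- unlist(obj$feature_names)
  rows <- lapply(obj$nodes, function(o) {
    leaf <- is.null(o$feature)
    data.frame(
      id = o$id,
      feature = if (leaf) NA_integer_ else match(o$feature, feats),
      threshold = if (leaf) NA_real_ else as.numeric(o$threshold),
      left = if (leaf) NA_integer_ else as.integer(o$left),
      right = if (leaf) NA_integer_ else as.integer(o$right),
      value = as.numeric(o$value), n = as.numeric(o$n_samples),
      impurity = if (is.null(o$impurity)) NA_real_ else as.numeric(o$impurity),
      gain = NA_real_)
  })
  tree_model(do.call(rbind, rows), feats,
             value_space = obj$value_space, split_rule = obj$split_rule,
             root_id = obj$root_id)
}
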