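# Hollow-tree Super (HOTS): cross-validated, signed, per-class feature
# importance for boosted binary classifiers.
#
# Per fold: fit a boosted ensemble on the training split, decompose every
# test-split prediction into per-feature log-odds contributions, keep only
# correct predictions made with confidence, orient contributions to the
# predicted class and split them by class, average per feature within each
# class, then attach a direction to each feature from the sign of its
# class-mean difference on the test split. Fold results are averaged and a
# per-feature fold-appearance count is reported.

#' Retain correct, confident predictions
#'
#' Keeps exactly the samples whose predicted class equals the true class and
#' whose confidence — the probability assigned to the predicted class,
#' `max(p, 1 - p)` — is at least `threshold`. Predictions at exactly the
#' threshold are retained; only strictly less confident ones are dropped.
#'
#' @param d a `decomposition` carrying `true_class`.
#' @param threshold minimum confidence in `[0, 1]` (default 0.7).
#' @return the filtered `decomposition`.
#' @export
filter_predictions <- function(d, threshold = 0.7) {
  stopifnot(inherits(d, "decomposition"), threshold >= 0, threshold <= 1)
  if (is.null(d$true_class)) stop("decomposition carries no true_class; pass y to decompose()")
  confidence <- pmax(d$probability, 1 - d$probability)
  subset_decomposition(d, d$predicted_class == d$true_class & confidence >= threshold)
}

#' Partition decompositions by predicted class
#'
#' Orients contributions to each sample's predicted class, then splits the
#' set into the positive-class (predicted 1) and negative-class (predicted 0)
#' partitions. After [filter_predictions()] the predicted class equals the
#' true class, so the partitions correspond to the two outcome groups.
#'
#' @param d a `decomposition` in log-odds space.
#' @return list with elements `positive` and `negative`, each a
#'   `decomposition`.
#' @export
split_by_class <- function(d) {
  stopifnot(inherits(d, "decomposition"))
  if (!d$oriented) d <- orient_to_predicted_class(d)
  list(positive = subset_decomposition(d, d$predicted_class == 1L),
       negative = subset_decomposition(d, d$predicted_class == 0L))
}

#' Average contributions per feature
#'
#' Sums contributions by feature over all retained predictions in one class
#' partition and divides by the number of those predictions, giving the
#' average weight of each feature per prediction. An empty partition yields
#' all-zero weights with a warning.
#'
#' @param d a `decomposition` (one class partition, oriented).
#' @return named numeric vector, one weight per feature.
#' @export
aggregate_weights <- function(d) {
  stopifnot(inherits(d, "decomposition"))
  if (n_samples(d) == 0L) {
    warning("no retained predictions in this partition; weights set to 0")
    return(structure(numeric(length(d$feature_names)), names = d$feature_names))
  }
  colMeans(d$contributions)
}

#' Attach a direction to per-class feature weights
#'
#' For each feature the sign `s = sign(mean(X[f] | y = 1) - mean(X[f] | y = 0))`
#' is computed from labelled samples. Positive-class weights are multiplied
#' by `s` and negative-class weights by `-s`, turning magnitude-only log-odds
#' weights into directional ones: a positive signed weight means larger
#' feature values push toward that class. Features with exactly equal class
#' means get sign 0 (weight zeroed) with a warning.
#'
#' @param pos_w,neg_w named per-feature weight vectors for the positive and
#'   negative class partitions.
#' @param X feature matrix of the labelled samples used for the class means.
#' @param y their true 0/1 labels; both classes must be present.
#' @return list with `positive_weights` and `negative_weights` (signed) and
#'   the `sign` vector used.
#' @export
infer_signs <- function(pos_w, neg_w, X, y) {
  X <- as_feature_matrix(X)
  y <- check_labels(y, nrow(X), require_both_classes = FALSE)
  if (length(unique(y)) < 2L) stop("cannot compute class means: a class is absent")
  stopifnot(length(pos_w) == ncol(X), length(neg_w) == ncol(X))
  s <- sign(colMeans(X[y == 1L, , drop = FALSE]) -
              colMeans(X[y == 0L, , drop = FALSE]))
  if (any(s == 0)) {
    warning("equal class means for feature(s) ",
            paste(colnames(X)[s == 0], collapse = ", "),
            "; their signed weights are 0")
  }
  list(positive_weights = pos_w * s, negative_weights = neg_w * -s, sign = s)
}

# Stratified fold ids: within each class, a seeded shuffle then round-robin
# assignment, so every fold's test split keeps both classes when possible.
make_folds <- function(y, k, stratified = TRUE) {
  fold <- integer(length(y))
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(length(y))] <- rep_len(seq_len(k), length(y))
  }
  fold
}

#' Cross-validated directional feature importance (HOTS)
#'
#' Fits a boosted tree ensemble in each of `k` stratified cross-validation
#' folds and turns the per-prediction log-odds decompositions of the held-out
#' samples into signed per-class feature importances: incorrect and
#' low-confidence predictions are discarded, contributions are oriented to
#' the predicted class and averaged per feature within each class, and each
#' feature's direction is inferred from the sign of its class-mean difference
#' on the held-out split. Fold-level importances are averaged (over all folds
#' by default, treating folds where a feature is absent as 0 so magnitudes
#' stay comparable) and each feature's fold-appearance count is reported.
#'
#' @param X numeric feature matrix or data frame, one sample per row.
#' @param y 0/1 labels; the positive class is 1.
#' @param k number of cross-validation folds (default 5).
#' @param prob_threshold minimum confidence for a prediction to be retained
#'   (default 0.7).
#' @param stratified stratify fold assignment by class (default `TRUE`).
#' @param fold_average `"all_folds"` divides the cross-fold sum by `k`;
#'   `"present_folds"` divides by the number of folds in which the feature
#'   appears.
#' @param appearance_epsilon weight magnitude above which a feature counts as
#'   appearing in a fold.
#' @param seed integer seed for fold assignment (training itself is
#'   deterministic).
#' @param folds optional explicit fold assignment (integer vector in
#'   `1..k`), overriding `stratified`/`seed`.
#' @param n_trees,learning_rate,max_depth,min_samples_split,lambda,base_score
#'   passed to [boosted_trees()].
#' @return object of class `hots` with elements `per_fold` (per-fold signed
#'   weight vectors and retention counts), `mean_positive`, `mean_negative`,
#'   `fold_counts`, `per_fold_accuracy`, `mean_accuracy`, plus the fold
#'   assignment and configuration. Has `print`, `summary`, `coef` and `plot`
#'   methods.
#' @examples
#' d <- make_synthetic(n_samples = 120, n_features = 4, informative = 1,
#'                     mean_shift = 2.5, seed = 7)
#' fit <- hots(d$X, d$y, k = 3, n_trees = 15, max_depth = 2, seed = 7)
#' summary(fit)
#' @export
hots <- function(X, y, k = 5L, prob_threshold = 0.7, stratified = TRUE,
                 fold_average = c("all_folds", "present_folds"),
                 appearance_epsilon = 1e-12, seed = 1L, folds = NULL,
                 n_trees = 100L, learning_rate = 0.3, max_depth = 6L,
                 min_samples_split = 2L, lambda = 1, base_score = 0) {
  cl <- match.call()
  fold_average <- match.arg(fold_average)
  X <- as_feature_matrix(X)
  y <- check_labels(y, nrow(X))
  stopifnot(k >= 2, prob_threshold >= 0, prob_threshold <= 1,
            appearance_epsilon >= 0)
  if (min(table(y)) < k) stop("too few samples: need at least k per class")

  if (is.null(folds)) {
    if (!is.null(seed)) set.seed(seed)
    folds <- make_folds(y, k, stratified)
  } else {
    folds <- as.integer(folds)
    if (length(folds) != length(y) || !all(folds %in% seq_len(k))) {
      stop("folds must assign every sample to a fold in 1..k")
    }
  }

  feats <- colnames(X)
  per_fold <- vector("list", k)
  acc <- numeric(k)
  for (i in seq_len(k)) {
    test <- folds == i
    fit <- boosted_trees(X[!test, , drop = FALSE], y[!test],
                         n_trees = n_trees, learning_rate = learning_rate,
                         max_depth = max_depth,
                         min_samples_split = min_samples_split,
                         lambda = lambda, base_score = base_score)
    d <- decompose(fit, X[test, , drop = FALSE], y = y[test])
    acc[i] <- mean(d$predicted_class == d$true_class)
    kept <- filter_predictions(d, prob_threshold)
    parts <- split_by_class(kept)
    pos_w <- suppressWarnings(aggregate_weights(parts$positive))
    neg_w <- suppressWarnings(aggregate_weights(parts$negative))
    signed <- infer_signs(pos_w, neg_w, X[test, , drop = FALSE], y[test])
    per_fold[[i]] <- list(positive_weights = signed$positive_weights,
                          negative_weights = signed$negative_weights,
                          n_retained_pos = n_samples(parts$positive),
                          n_retained_neg = n_samples(parts$negative),
                          fold_index = i)
  }

  pos_mat <- do.call(rbind, lapply(per_fold, `[[`, "positive_weights"))
  neg_mat <- do.call(rbind, lapply(per_fold, `[[`, "negative_weights"))
  present <- pmax(abs(pos_mat), abs(neg_mat)) > appearance_epsilon
  counts <- colSums(present)
  denom <- if (fold_average == "all_folds") rep(k, length(feats)) else pmax(counts, 1L)
  res <- structure(
    list(per_fold = per_fold,
         mean_positive = colSums(pos_mat) / denom,
         mean_negative = colSums(neg_mat) / denom,
         fold_counts = structure(as.integer(counts), names = feats),
         per_fold_accuracy = acc,
         mean_accuracy = mean(acc),
         folds = folds, feature_names = feats, k = as.integer(k),
         prob_threshold = prob_threshold, fold_average = fold_average,
         appearance_epsilon = appearance_epsilon, seed = seed, call = cl),
    class = "hots")
  res
}

#' Fold-appearance counts of a HOTS fit
#'
#' Number of cross-validation folds in which each feature carries a nonzero
#' aggregated weight (magnitude above the configured epsilon) in either
#' class.
#'
#' @param object a `hots` fit.
#' @return named integer vector in `0..k`.
#' @export
fold_counts <- function(object) {
  stopifnot(inherits(object, "hots"))
  object$fold_counts
}

#' @export
print.hots <- function(x, ...) {
  cat(sprintf("HOTS feature importance: %d features, %d-fold CV, confidence threshold %.2f\n",
              length(x$feature_names), x$k, x$prob_threshold))
  cat(sprintf("mean held-out accuracy: %.3f\n", x$mean_accuracy))
  top <- order(-pmax(abs(x$mean_positive), abs(x$mean_negative)))
  top <- top[seq_len(min(10L, length(top)))]
  df <- data.frame(feature = x$feature_names[top],
                   mean_positive = round(x$mean_positive[top], 4),
                   mean_negative = round(x$mean_negative[top], 4),
                   fold_count = x$fold_counts[top], row.names = NULL)
  print(df)
  invisible(x)
}

#' Summarize a HOTS fit as a per-feature table
#'
#' @param object a `hots` fit.
#' @param ... unused.
#' @return data.frame with one row per feature: mean signed weight for each
#'   class, fold count, and the per-fold signed positive/negative weights
#'   (the per-fold layout of the published tables), ordered by weight
#'   magnitude.
#' @export
summary.hots <- function(object, ...) {
  x <- object
  pos_mat <- do.call(rbind, lapply(x$per_fold, `[[`, "positive_weights"))
  neg_mat <- do.call(rbind, lapply(x$per_fold, `[[`, "negative_weights"))
  df <- data.frame(feature = x$feature_names,
                   mean_positive = unname(x$mean_positive),
                   mean_negative = unname(x$mean_negative),
                   fold_count = unname(x$fold_counts), row.names = NULL)
  pf <- t(pos_mat); nf <- t(neg_mat)          # features x folds
  colnames(pf) <- paste0("pos_fold", seq_len(x$k))
  colnames(nf) <- paste0("neg_fold", seq_len(x$k))
  df <- cbind(df, as.data.frame(pf, row.names = FALSE),
              as.data.frame(nf, row.names = FALSE))
  df[order(-pmax(abs(df$mean_positive), abs(df$mean_negative))), , drop = FALSE]
}

#' Extract mean signed weights
#'
#' @param object a `hots` fit.
#' @param class `"positive"`, `"negative"`, or `"both"` (a two-column matrix).
#' @param ... unused.
#' @return named numeric vector, or matrix when `class = "both"`.
#' @export
coef.hots <- function(object, class = c("both", "positive", "negative"), ...) {
  class <- match.arg(class)
  switch(class,
         positive = object$mean_positive,
         negative = object$mean_negative,
         both = cbind(positive = object$mean_positive,
                      negative = object$mean_negative))
}

#' Plot HOTS importances
#'
#' Horizontal bar chart of the mean signed weight per feature for one class,
#' ordered by magnitude, log-odds on the x axis.
#'
#' @param x a `hots` fit.
#' @param class which class's weights to draw.
#' @param top_n show at most this many features.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted weights.
#' @export
plot.hots <- function(x, class = c("positive", "negative"), top_n = 20L, ...) {
  class <- match.arg(class)
  w <- if (class == "positive") x$mean_positive else x$mean_negative
  ord <- order(abs(w), decreasing = TRUE)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  w <- rev(w[ord])
  graphics::barplot(w, horiz = TRUE, las = 1,
                    xlab = "mean feature contribution (log odds)",
                    main = sprintf("HOTS importance, %s class", class), ...)
  invisible(w)
}

#' Write a HOTS report to disk
#'
#' Writes `importance.tsv` (feature, mean weights, fold count, per-fold
#' columns), `metrics.json` (per-fold and mean accuracy) and `run_log.txt`
#' (configuration echo) into `dir`.
#'
#' @param object a `hots` fit.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_hots_report <- function(object, dir) {
  stopifnot(inherits(object, "hots"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(importance = file.path(dir, "importance.tsv"),
             metrics = file.path(dir, "metrics.json"),
             log = file.path(dir, "run_log.txt"))
  utils::write.table(summary(object), paths[["importance"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(per_fold = lapply(seq_len(object$k), function(i) {
      list(accuracy = object$per_fold_accuracy[i])
    }),
    mean = list(accuracy = object$mean_accuracy)),
    paths[["metrics"]], auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("hollowtree HOTS run, %s", format(Sys.time())),
               sprintf("k = %d, prob_threshold = %g, fold_average = %s, seed = %s",
                       object$k, object$prob_threshold, object$fold_average,
                       deparse(object$seed)),
               sprintf("call: %s", deparse1(object$call))),
             paths[["log"]])
  invisible(paths)
}
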