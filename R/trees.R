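# Tree baselines used for preprocessing ablations, feature screening and
# as the fast fitness classifier: a compact CART (Gini impurity,
# depth-limited) and a bagged random forest with per-tree feature
# subsampling. Implemented here because no tree package ships with the
# target environment; the surface mirrors the usual fit/predict pair.

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

best_split <- function(X, y, K, feat_idx, min_leaf) {
  n <- length(y)
  total <- tabulate(y, K)
  parent <- gini_impurity(total)
  best <- list(gain = 0)
  for (f in feat_idx) {
    xs <- X[, f]
    ord <- order(xs)
    ys <- y[ord]
    xo <- xs[ord]
    # cumulative class counts at each candidate cut
    left <- matrix(0, n, K)
    left[cbind(seq_len(n), ys)] <- 1
    left <- apply(left, 2, cumsum)
    cut_ok <- which(diff(xo) > 0)
    cut_ok <- cut_ok[cut_ok >= min_leaf & (n - cut_ok) >= min_leaf]
    if (!length(cut_ok)) next
    nl <- cut_ok
    nr <- n - nl
    gl <- 1 - rowSums((left[cut_ok, , drop = FALSE] / nl)^2)
    right <- matrix(total, length(cut_ok), K, byrow = TRUE) - left[cut_ok, , drop = FALSE]
    gr <- 1 - rowSums((right / nr)^2)
    gain <- parent - (nl * gl + nr * gr) / n
    i <- which.max(gain)
    if (gain[i] > best$gain + 1e-12) {
      best <- list(gain = gain[i], feature = f,
                   threshold = (xo[cut_ok[i]] + xo[cut_ok[i] + 1L]) / 2)
    }
  }
  best
}

cart_grow <- function(X, y, K, depth, max_depth, min_split, min_leaf, mtry) {
  counts <- tabulate(y, K)
  node <- list(counts = counts, prediction = which.max(counts))
  if (depth >= max_depth || length(y) < min_split || gini_impurity(counts) == 0)
    return(node)
  feat_idx <- if (is.null(mtry) || mtry >= ncol(X)) seq_len(ncol(X))
              else sample(ncol(X), mtry)
  sp <- best_split(X, y, K, feat_idx, min_leaf)
  if (sp$gain <= 0) return(node)
  go_left <- X[, sp$feature] <= sp$threshold
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$left <- cart_grow(X[go_left, , drop = FALSE], y[go_left], K,
                         depth + 1L, max_depth, min_split, min_leaf, mtry)
  node$right <- cart_grow(X[!go_left, , drop = FALSE], y[!go_left], K,
                          depth + 1L, max_depth, min_split, min_leaf, mtry)
  node
}

#' Fit a CART decision tree (Gini)
#'
#' @param X n x d numeric feature matrix.
#' @param labels class labels.
#' @param max_depth maximum tree depth.
#' @param min_split minimum node size to attempt a split.
#' @param min_leaf minimum leaf size.
#' @param mtry optional number of features sampled per node (used by the
#'   forest).
#' @return an `endo_cart`.
#' @export
cart_train <- function(X, labels, max_depth = 10L, min_split = 4L,
                       min_leaf = 1L, mtry = NULL) {
  classes <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes)
  root <- cart_grow(as.matrix(X), y, length(classes), 0L, max_depth,
                    min_split, min_leaf, mtry)
  structure(list(root = root, classes = classes), class = "endo_cart")
}

cart_predict_one <- function(node, x) {
  while (!is.null(node$feature)) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$prediction
}

#' @export
predict.endo_cart <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  idx <- vapply(seq_len(nrow(X)), function(i) cart_predict_one(object$root, X[i, ]),
                integer(1))
  factor(object$classes[idx], levels = object$classes)
}

#' Fit a bagged random forest of CART trees
#'
#' Bootstrap resampling plus per-node feature subsampling
#' (`mtry = sqrt(d)` by default); prediction by majority vote.
#'
#' @param X n x d numeric feature matrix.
#' @param labels class labels.
#' @param n_trees number of trees.
#' @param mtry features sampled per node.
#' @param max_depth per-tree depth limit.
#' @param seed integer seed.
#' @return an `endo_forest`.
#' @export
forest_train <- function(X, labels, n_trees = 15L, mtry = NULL,
                         max_depth = 12L, seed = 0L) {
  X <- as.matrix(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  classes <- sort(unique(as.character(labels)))
  withr_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(i) {
      idx <- sample(nrow(X), nrow(X), replace = TRUE)
      cart_train(X[idx, , drop = FALSE], as.character(labels)[idx],
                 max_depth = max_depth, mtry = mtry)
    })
    structure(list(trees = trees, classes = classes), class = "endo_forest")
  })
}

#' @export
predict.endo_forest <- function(object, newdata, ...) {
  votes <- vapply(object$trees, function(tr)
    as.character(predict(tr, newdata)), character(nrow(as.matrix(newdata))))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  pick <- apply(votes, 1, function(v) names(which.max(table(factor(v, levels = object$classes)))))
  factor(pick, levels = object$classes)
}

stratified_split <- function(labels, test_frac = 0.2, seed = 0L) {
  labels <- as.character(labels)
  withr_seed(seed, {
    test <- unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      n_test <- max(1L, round(length(idx) * test_frac))
      if (length(idx) <= 1L) return(integer(0))   # keep singletons in train
      sample(idx, min(n_test, length(idx) - 1L))
    }))
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

#' Score a feature set with a tree baseline
#'
#' Stratified 80/20 split, fits the named baseline on the training part
#' and returns the held-out macro F1. Used for preprocessing ablations
#' and feature screening.
#'
#' @param features n x d matrix.
#' @param labels class labels.
#' @param baseline `"decision_tree"` or `"random_forest"`.
#' @param seed split (and forest) seed.
#' @return held-out macro F1.
#' @export
evaluate_feature_set <- function(features, labels,
                                 baseline = c("decision_tree", "random_forest"),
                                 seed = 0L) {
  baseline <- match.arg(baseline)
  features <- as.matrix(features)
  labels <- as.character(labels)
  sp <- stratified_split(labels, 0.2, seed)
  fit <- if (baseline == "decision_tree")
    cart_train(features[sp$train, , drop = FALSE], labels[sp$train])
  else
    forest_train(features[sp$train, , drop = FALSE], labels[sp$train], seed = seed)
  pred <- as.character(predict(fit, features[sp$test, , drop = FALSE]))
  classes <- sort(unique(labels))
  f1_macro(confusion(match(labels[sp$test], classes), match(pred, classes),
                     length(classes)))
}

#' Random-combination descriptor selection
#'
#' Evaluates `n_trials` random descriptor subsets with the decision-tree
#' baseline, always also evaluating the published selected set (when its
#' descriptors are present in the bank matrix) and the full set; returns
#' the best subset by validation macro F1, ties broken toward fewer
#' total dimensions.
#'
#' @param features bank matrix with a `spans` attribute (from
#'   [extract_bank_matrix()], possibly with a deep-feature span).
#' @param labels class labels.
#' @param n_trials number of random subsets (>= 1).
#' @param seed integer seed.
#' @return list with `selected` (descriptor names), `f1`, and the
#'   per-candidate `trace` data.frame.
#' @export
select_features <- function(features, labels, n_trials = 10L, seed = 0L) {
  spans <- attr(features, "spans")
  if (is.null(spans)) stop("features must carry a spans attribute", call. = FALSE)
  all_names <- names(spans)
  candidates <- list(all_names)
  published <- intersect(selected_descriptors(), all_names)
  if (length(published)) candidates <- c(candidates, list(published))
  withr_seed(seed, {
    for (i in seq_len(n_trials)) {
      k <- sample(seq_along(all_names), 1L)
      candidates <- c(candidates, list(sort(sample(all_names, k))))
    }
    candidates <- unique(candidates)
    trace <- data.frame(subset = vapply(candidates, paste, character(1), collapse = "+"),
                        dims = vapply(candidates, function(nm) sum(lengths(spans[nm])),
                                      integer(1)),
                        f1 = NA_real_)
    for (i in seq_along(candidates)) {
      cols <- unlist(spans[candidates[[i]]])
      trace$f1[i] <- evaluate_feature_set(features[, cols, drop = FALSE], labels,
                                          "decision_tree", seed = seed)
    }
    best_f1 <- max(trace$f1)
    tied <- which(trace$f1 >= best_f1 - 1e-12)
    best <- tied[which.min(trace$dims[tied])]
    list(selected = candidates[[best]], f1 = trace$f1[best], trace = trace)
  })
}
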