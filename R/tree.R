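# Minimal Gini classification tree (CART) with an absolute impurity
# threshold. The no-split event -- no candidate split at the root clears
# `min_impurity_decrease` -- yields a constant predictor, which is the
# failure mechanism of the coverage study: a constant score gives AUC
# exactly 0.5 under the tie rule, and 15 identical AUCs give the naive
# t-interval a zero sample variance.

#' Tree hyperparameters
#'
#' @param max_depth Maximum tree depth (root split = depth 1).
#' @param min_samples_leaf Minimum observations in each child of a split.
#' @param min_impurity_decrease Minimum decrease in mean Gini impurity a
#'   split must achieve to be made; governs how easily the tree declines to
#'   split at all.
#' @return A list of class `tree_params`.
#' @export
tree_params <- function(max_depth = 2L, min_samples_leaf = 10L,
                        min_impurity_decrease = 0.1) {
  stopifnot(max_depth >= 1, min_samples_leaf >= 1,
            min_impurity_decrease >= 0)
  structure(list(max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 min_impurity_decrease = min_impurity_decrease),
            class = "tree_params")
}

gini_impurity <- function(y) {
  p <- mean(y)
  2 * p * (1 - p)
}

# Best single split of (X, y): returns NULL when no split with both
# children >= min_leaf decreases mean impurity by more than min_dec.
best_split <- function(X, y, min_leaf, min_dec) {
  n <- length(y)
  g0 <- gini_impurity(y)
  best <- list(dec = min_dec)
  found <- FALSE
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xs <- X[o, j]; ys <- y[o]
    nl <- seq_len(n - 1L)
    c1 <- cumsum(ys)[nl]
    p1l <- c1 / nl; p1r <- (sum(y) - c1) / (n - nl)
    dec <- g0 - (nl * 2 * p1l * (1 - p1l) +
                   (n - nl) * 2 * p1r * (1 - p1r)) / n
    valid <- (xs[nl] < xs[nl + 1L]) & nl >= min_leaf & (n - nl) >= min_leaf
    dec[!valid] <- -Inf
    i <- which.max(dec)
    if (is.finite(dec[i]) && dec[i] > best$dec) {
      found <- TRUE
      best <- list(dec = dec[i], feature = j,
                   threshold = (xs[i] + xs[i + 1L]) / 2)
    }
  }
  if (found) best else NULL
}

grow_node <- function(X, y, depth, params) {
  node <- list(prob = mean(y), n = length(y))
  sp <- if (depth <= params$max_depth &&
            length(y) >= 2L * params$min_samples_leaf)
    best_split(X, y, params$min_samples_leaf, params$min_impurity_decrease)
  else NULL
  if (is.null(sp)) {
    node$leaf <- TRUE
    return(node)
  }
  left <- X[, sp$feature] <= sp$threshold
  node$leaf <- FALSE
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$left <- grow_node(X[left, , drop = FALSE], y[left], depth + 1L, params)
  node$right <- grow_node(X[!left, , drop = FALSE], y[!left], depth + 1L,
                          params)
  node
}

#' Train a Gini classification tree
#'
#' Greedy binary recursive partitioning on the Gini criterion, bounded by
#' [tree_params()]. When no root split achieves an impurity decrease above
#' `min_impurity_decrease`, the returned model is a constant predictor
#' (every score equal to the training class-1 frequency).
#'
#' @param features Numeric matrix of predictors.
#' @param labels Binary (0/1) labels; both classes must be present.
#' @param params A [tree_params()].
#' @return An object of class `gini_tree`; score new data with
#'   [predict_scores()].
#' @export
train_tree <- function(features, labels, params = tree_params()) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stopf("both classes must be present in `labels`")
  if (nrow(features) != length(labels))
    stopf("`features` and `labels` disagree in length")
  root <- grow_node(features, labels, 1L, params)
  structure(list(root = root, params = params,
                 n_features = ncol(features)),
            class = "gini_tree")
}

#' @rdname train_tree
#' @param model A `gini_tree`.
#' @export
is_constant_model <- function(model) {
  stopifnot(inherits(model, "gini_tree"))
  isTRUE(model$root$leaf)
}

score_one <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  node$prob
}

#' Score observations with a trained tree
#'
#' @param model A `gini_tree` from [train_tree()].
#' @param features Numeric matrix of new observations.
#' @return Numeric vector of class-1 scores (leaf class-1 frequencies).
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "gini_tree"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stopf("feature count mismatch: model has %d, data has %d",
          model$n_features, ncol(features))
  apply(features, 1L, function(x) score_one(model$root, x))
}
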