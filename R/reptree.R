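#' Parameters of the reduced-error-pruning regression tree
#'
#' The tree is grown greedily by variance reduction and then pruned bottom-up
#' against an internal held-out fold: a split node is collapsed to a leaf
#' whenever the pruning-set squared error does not increase. Defaults mirror
#' the common implementation of this learner: minimum 2 instances per leaf,
#' 3 internal folds (one held out for pruning), unlimited depth.
#'
#' @param min_instances_per_leaf minimum rows in any leaf (>= 1).
#' @param n_pruning_folds internal folds; one is held out as the pruning set
#'   (>= 2 when pruning is enabled).
#' @param max_depth maximum tree depth (`Inf` = unlimited; depth 0 = root).
#' @param min_variance_prop a node is not split when its target variance
#'   falls below this fraction of the root variance.
#' @param prune logical; disable to grow an unpruned tree on all rows.
#' @param backfit after pruning, pass the pruning fold back down the tree and
#'   update leaf values with the combined data (no-op when `prune = FALSE`).
#' @param seed integer seed for the internal fold assignment.
#' @return an object of class `reptree_params`.
#' @export
reptree_params <- function(min_instances_per_leaf = 2, n_pruning_folds = 3,
                           max_depth = Inf, min_variance_prop = 1e-3,
                           prune = TRUE, backfit = TRUE, seed = 1L) {
  check_that(min_instances_per_leaf >= 1, "min_instances_per_leaf must be >= 1")
  check_that(!prune || n_pruning_folds >= 2,
             "n_pruning_folds must be >= 2 when pruning is enabled")
  check_that(min_variance_prop >= 0, "min_variance_prop must be >= 0")
  structure(list(min_instances_per_leaf = as.integer(min_instances_per_leaf),
                 n_pruning_folds = as.integer(n_pruning_folds),
                 max_depth = max_depth, min_variance_prop = min_variance_prop,
                 prune = prune, backfit = backfit, seed = seed),
            class = "reptree_params")
}

# Best variance-reduction split for one node. Returns NULL when no valid
# split improves the SSE. Ties (within 1e-12) break to the lowest feature
# index, then the lowest threshold.
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  sse_total <- sum(y^2) - sum(y)^2 / n
  best <- NULL
  best_gain <- 1e-12
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    ys <- y[ord]
    cs <- cumsum(ys)
    cq <- cumsum(ys^2)
    i <- seq_len(n - 1)
    valid <- (xs[i] < xs[i + 1]) & (i >= min_leaf) & ((n - i) >= min_leaf)
    if (!any(valid)) next
    i <- i[valid]
    sse_l <- cq[i] - cs[i]^2 / i
    sse_r <- (cq[n] - cq[i]) - (cs[n] - cs[i])^2 / (n - i)
    gains <- sse_total - sse_l - sse_r
    k <- which(gains > max(gains) - 1e-12)[1]  # lowest threshold among ties
    if (gains[k] > best_gain + 1e-12) {
      best_gain <- gains[k]
      best <- list(feature = j, threshold = (xs[i[k]] + xs[i[k] + 1]) / 2,
                   gain = gains[k])
    }
  }
  best
}

grow_tree <- function(X, y, min_leaf, max_depth, min_var = 0, depth = 0) {
  node <- list(type = "leaf", value = mean(y), n = length(y))
  if (length(y) < 2 * min_leaf || depth >= max_depth ||
      stats::var(y) < max(1e-24, min_var)) {
    return(node)
  }
  sp <- best_split(X, y, min_leaf)
  if (is.null(sp)) return(node)
  go_left <- X[, sp$feature] < sp$threshold
  list(type = "split", feature = sp$feature, threshold = sp$threshold,
       value = mean(y), n = length(y),
       left = grow_tree(X[go_left, , drop = FALSE], y[go_left],
                        min_leaf, max_depth, min_var, depth + 1),
       right = grow_tree(X[!go_left, , drop = FALSE], y[!go_left],
                         min_leaf, max_depth, min_var, depth + 1))
}

# Reduced-error pruning: collapse any split whose pruning-set SSE as a leaf
# (predicting the grow-set node mean) does not exceed its subtree's SSE.
# Nodes reached by no pruning rows collapse (SSE 0 either way).
prune_tree <- function(node, Xp, yp) {
  sse_as_leaf <- sum((yp - node$value)^2)
  if (node$type == "leaf") {
    return(list(node = node, sse = sse_as_leaf))
  }
  go_left <- if (length(yp) > 0) Xp[, node$feature] < node$threshold else logical(0)
  l <- prune_tree(node$left, Xp[go_left, , drop = FALSE], yp[go_left])
  r <- prune_tree(node$right, Xp[!go_left, , drop = FALSE], yp[!go_left])
  sse_split <- l$sse + r$sse
  if (sse_as_leaf <= sse_split + 1e-12) {
    list(node = list(type = "leaf", value = node$value, n = node$n),
         sse = sse_as_leaf)
  } else {
    node$left <- l$node
    node$right <- r$node
    list(node = node, sse = sse_split)
  }
}

# Backfitting: route extra rows down the pruned tree and update each leaf
# value to the mean of all (grow + pruning) rows reaching it.
backfit_tree <- function(node, X_all, y_all) {
  if (node$type == "leaf") {
    if (length(y_all) > 0) {
      node$value <- mean(y_all)
      node$n <- length(y_all)
    }
    return(node)
  }
  go_left <- X_all[, node$feature] < node$threshold
  node$left <- backfit_tree(node$left, X_all[go_left, , drop = FALSE],
                            y_all[go_left])
  node$right <- backfit_tree(node$right, X_all[!go_left, , drop = FALSE],
                             y_all[!go_left])
  node
}

#' Fit a reduced-error-pruning regression tree
#'
#' Rows are split into `n_pruning_folds` seeded folds; the tree is grown on
#' all but the first fold by greedy variance reduction and pruned against the
#' held-out fold: a split is collapsed whenever the pruning-fold squared
#' error does not increase. With backfitting enabled (the default), the
#' pruning fold is then passed down the pruned tree and leaf values are
#' re-estimated from the combined data. A constant target yields a root-only
#' tree.
#'
#' @param X data.frame or matrix of numeric predictors.
#' @param y numeric target vector.
#' @param params a [reptree_params()].
#' @return an object of class `reptree` (fields `root`, `features`,
#'   `params`).
#' @export
fit_reptree <- function(X, y, params = reptree_params()) {
  stopifnot(inherits(params, "reptree_params"))
  X <- as.matrix(X)
  check_that(is.numeric(X) && !anyNA(X) && !anyNA(y),
             "predictors and target must be numeric with no missing values")
  check_that(nrow(X) == length(y), "X rows must match length(y)")
  check_that(length(y) >= 2 * params$min_instances_per_leaf,
             "need at least 2 * min_instances_per_leaf rows")
  n <- length(y)
  do_prune <- params$prune && n >= 2 * params$n_pruning_folds
  if (do_prune) {
    folds <- with_substream(params$seed, "reptree_folds",
                            expr = sample(rep_len(seq_len(params$n_pruning_folds), n)))
    grow_idx <- which(folds != 1L)
    prune_idx <- which(folds == 1L)
  } else {
    grow_idx <- seq_len(n)
    prune_idx <- integer(0)
  }
  y_grow <- y[grow_idx]
  min_var <- if (length(y_grow) > 1) {
    params$min_variance_prop * stats::var(y_grow)
  } else {
    0
  }
  root <- grow_tree(X[grow_idx, , drop = FALSE], y_grow,
                    params$min_instances_per_leaf, params$max_depth, min_var)
  if (do_prune) {
    root <- prune_tree(root, X[prune_idx, , drop = FALSE], y[prune_idx])$node
    if (isTRUE(params$backfit)) {
      root <- backfit_tree(root, X, y)
    }
  }
  structure(list(root = root, features = colnames(X), params = params),
            class = "reptree")
}

predict_node <- function(node, X) {
  if (node$type == "leaf") return(rep(node$value, nrow(X)))
  out <- numeric(nrow(X))
  go_left <- X[, node$feature] < node$threshold
  if (any(go_left)) out[go_left] <- predict_node(node$left, X[go_left, , drop = FALSE])
  if (any(!go_left)) out[!go_left] <- predict_node(node$right, X[!go_left, , drop = FALSE])
  out
}

#' @export
predict.reptree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features)) {
    check_that(all(object$features %in% colnames(X)),
               "newdata is missing training features")
    X <- X[, object$features, drop = FALSE]
  }
  predict_node(object$root, X)
}

# Number of leaves -- used by tests and usage summaries.
count_leaves <- function(node) {
  if (node$type == "leaf") return(1L)
  count_leaves(node$left) + count_leaves(node$right)
}

#' Number of leaves of a fitted tree
#' @param tree a `reptree`.
#' @return integer leaf count.
#' @export
n_leaves <- function(tree) count_leaves(tree$root)
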