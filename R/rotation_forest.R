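#' Parameters of the rotation-forest regressor
#'
#' Each tree of the ensemble sees the features rotated: the feature set is
#' randomly partitioned into groups of at most `feature_subset_size`, a
#' principal-axes rotation is estimated per group on a bootstrap row sample,
#' and the block-diagonal rotation is applied before training one
#' reduced-error-pruning tree. Predictions average over trees. The
#' class-dependent subsampling of the original classification algorithm has
#' no regression analogue; rows for axis estimation are drawn by plain
#' bootstrap.
#'
#' @param n_trees ensemble size.
#' @param feature_subset_size maximum features per rotation group; the last
#'   group may be smaller.
#' @param bootstrap_fraction fraction of rows (drawn with replacement) used to
#'   estimate each group's principal axes, in (0, 1].
#' @param tree_params a [reptree_params()].
#' @param identity_rotation force every rotation to the identity (diagnostic
#'   collapse mode: with one tree and one group, the forest equals the plain
#'   tree).
#' @param seed master integer seed.
#' @return an object of class `rotation_forest_params`.
#' @export
rotation_forest_params <- function(n_trees = 10, feature_subset_size = 3,
                                   bootstrap_fraction = 0.75,
                                   tree_params = reptree_params(),
                                   identity_rotation = FALSE, seed = 1L) {
  check_that(n_trees >= 1, "n_trees must be >= 1")
  check_that(feature_subset_size >= 1, "feature_subset_size must be >= 1")
  check_that(bootstrap_fraction > 0 && bootstrap_fraction <= 1,
             "bootstrap_fraction must be in (0, 1]")
  structure(list(n_trees = as.integer(n_trees),
                 feature_subset_size = as.integer(feature_subset_size),
                 bootstrap_fraction = bootstrap_fraction,
                 tree_params = tree_params,
                 identity_rotation = identity_rotation, seed = seed),
            class = "rotation_forest_params")
}

# Principal axes of a group estimated on a bootstrap sample. Always returns a
# p x p orthonormal matrix: eigen() of the covariance, identity on degenerate
# (zero-variance) groups. Eigenvector signs are fixed so the largest-magnitude
# entry of each axis is positive (determinism across platforms).
group_rotation <- function(Xg) {
  p <- ncol(Xg)
  S <- stats::cov(Xg)
  if (anyNA(S) || all(abs(S) < 1e-24)) {
    message("degenerate (zero-variance) rotation group: using identity axes")
    return(diag(p))
  }
  ev <- eigen(S, symmetric = TRUE)$vectors
  for (k in seq_len(p)) {
    m <- which.max(abs(ev[, k]))
    if (ev[m, k] < 0) ev[, k] <- -ev[, k]
  }
  ev
}

rotate_features <- function(X, groups, centers, rotations) {
  cols <- lapply(seq_along(groups), function(g) {
    sweep(X[, groups[[g]], drop = FALSE], 2, centers[[g]]) %*% rotations[[g]]
  })
  out <- do.call(cbind, cols)
  colnames(out) <- unlist(lapply(seq_along(groups), function(g) {
    paste0("g", g, "_pc", seq_along(groups[[g]]))
  }))
  out
}

#' Fit a rotation forest of reduced-error-pruning regression trees
#'
#' @param X data.frame or matrix of numeric predictors (named columns).
#' @param y numeric target.
#' @param params a [rotation_forest_params()].
#' @return an object of class `rotation_forest`: per-tree feature groupings,
#'   per-group centring vectors and orthonormal rotations, and the fitted
#'   trees; plus feature names and a training summary.
#' @export
fit_rotation_forest <- function(X, y, params = rotation_forest_params()) {
  stopifnot(inherits(params, "rotation_forest_params"))
  X <- as.matrix(X)
  check_that(!is.null(colnames(X)), "X must have column names")
  check_that(ncol(X) >= 1, "need at least one feature")
  check_that(nrow(X) >= 10, "need at least 10 rows")
  check_that(nrow(X) == length(y), "X rows must match length(y)")
  n <- nrow(X)
  p <- ncol(X)
  k <- min(params$feature_subset_size, p)

  members <- lapply(seq_len(params$n_trees), function(t) {
    with_substream(params$seed, "rf_tree", t, expr = {
      # identity mode is a diagnostic collapse: keep the original feature
      # order too, so split tie-breaking matches the plain tree exactly
      perm <- if (params$identity_rotation) seq_len(p) else sample(p)
      groups <- split(perm, ceiling(seq_along(perm) / k))
      groups <- lapply(groups, function(g) colnames(X)[g])
      centers <- vector("list", length(groups))
      rotations <- vector("list", length(groups))
      for (g in seq_along(groups)) {
        if (params$identity_rotation) {
          centers[[g]] <- rep(0, length(groups[[g]]))
          rotations[[g]] <- diag(length(groups[[g]]))
        } else {
          idx <- sample(n, max(2L, round(params$bootstrap_fraction * n)),
                        replace = TRUE)
          sub <- X[idx, groups[[g]], drop = FALSE]
          centers[[g]] <- colMeans(sub)
          rotations[[g]] <- group_rotation(sub)
        }
      }
      Xr <- rotate_features(X, groups, centers, rotations)
      tp <- params$tree_params
      tp$seed <- derive_seed(params$seed, "rf_tree_fit", t)
      tree <- fit_reptree(Xr, y, tp)
      list(groups = groups, centers = centers, rotations = rotations,
           tree = tree)
    })
  })

  structure(list(members = members, features = colnames(X), params = params,
                 training = list(n = n, p = p, y_mean = mean(y))),
            class = "rotation_forest")
}

#' @export
predict.rotation_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  check_that(all(object$features %in% colnames(X)),
             "newdata lacks feature(s): %s",
             paste(setdiff(object$features, colnames(X)), collapse = ", "))
  X <- X[, object$features, drop = FALSE]
  per_tree <- vapply(object$members, function(m) {
    Xr <- rotate_features(X, m$groups, m$centers, m$rotations)
    predict(m$tree, Xr)
  }, numeric(nrow(X)))
  per_tree <- matrix(per_tree, nrow = nrow(X))
  out <- rowMeans(per_tree)
  attr(out, "tree_sd") <- apply(per_tree, 1, stats::sd)
  out
}

#' Serialise a rotation forest to its JSON structure
#'
#' The model round-trips through a documented JSON object: feature names,
#' per-tree groups, centring vectors, rotation matrices and tree nodes.
#'
#' @param model a `rotation_forest`.
#' @param path optional file path; when given, JSON is written there.
#' @return the JSON string (invisibly when `path` is given).
#' @export
forest_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "rotation_forest"))
  payload <- list(
    features = model$features,
    training = model$training,
    members = lapply(model$members, function(m) {
      list(groups = m$groups,
           centers = lapply(m$centers, as.numeric),
           rotations = lapply(m$rotations, function(r) as.matrix(r)),
           tree = m$tree$root,
           tree_features = m$tree$features)
    })
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialise a rotation forest from JSON
#'
#' @param json a JSON string or file path produced by [forest_to_json()].
#' @return a `rotation_forest` usable with [predict.rotation_forest()].
#' @export
forest_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  rebuild_node <- function(nd) {
    if (nd$type == "leaf") {
      list(type = "leaf", value = nd$value, n = nd$n)
    } else {
      list(type = "split", feature = nd$feature, threshold = nd$threshold,
           value = nd$value, n = nd$n,
           left = rebuild_node(nd$left), right = rebuild_node(nd$right))
    }
  }
  members <- lapply(obj$members, function(m) {
    groups <- lapply(m$groups, unlist)
    list(groups = groups,
         centers = lapply(m$centers, unlist),
         rotations = lapply(seq_along(groups), function(g) {
           r <- m$rotations[[g]]
           if (is.matrix(r)) r else matrix(unlist(r), nrow = length(groups[[g]]))
         }),
         tree = structure(list(root = rebuild_node(m$tree),
                               features = unlist(m$tree_features),
                               params = NULL), class = "reptree"))
  })
  structure(list(members = members, features = unlist(obj$features),
                 params = NULL, training = obj$training),
            class = "rotation_forest")
}
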