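# Shared fixtures: everything built in code, scaled down where the full
# campaign geometry is not the thing under test.

# Camera with a tiny sensor: same optics/geometry arithmetic, cheap frames.
tiny_camera <- function(resolution = c(16L, 16L)) {
  camera_model(resolution = resolution)
}

# Two-date, two-block campaign: 2 x 3 x 2 x 3 = 36 samples per side.
small_design <- function() {
  campaign_design(n_dates = 2, n_blocks = 2)
}

# Reduced-scale end-to-end configuration (32x32 frames, centred 16-row ROI,
# small forest, 3 CV folds) that still exercises every stage.
small_config <- function(seed = 1L, ...) {
  run_config(
    design = small_design(),
    camera = tiny_camera(c(32L, 32L)),
    roi = roi_spec(height = 16),
    forest = rotation_forest_params(n_trees = 3,
                                    tree_params = reptree_params(seed = 1L)),
    n_folds = 3,
    seed = seed, ...)
}

# One ground-truth row with a chosen index value, for render tests.
truth_row <- function(cwsi = 0.5, date = 1L, treatment = "T1", block = 1L,
                      side = "east", vine = 1L, psi = -1.2) {
  data.frame(date = date, treatment = treatment, block = block, side = side,
             vine = vine, psi_stem = psi, true_cwsi = cwsi)
}

weather_row <- function(t_wet = 25, t_dry = 33, date = 1L, air_temp = 28) {
  data.frame(date = date, air_temp = air_temp, rh = 40,
             vpd = vpd_from_weather(air_temp, 40), irradiance = 850,
             t_wet = t_wet, t_dry = t_dry)
}

# Exhaustive minimal-SSE tree builder (min one row per leaf): the independent
# oracle for the greedy grower on tiny tables.
oracle_tree_sse <- function(X, y) {
  n <- length(y)
  sse <- sum((y - mean(y))^2)
  if (n < 2) return(sse)
  best <- sse
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (th in (xs[-1] + xs[-length(xs)]) / 2) {
      l <- X[, j] < th
      cand <- oracle_tree_sse(X[l, , drop = FALSE], y[l]) +
        oracle_tree_sse(X[!l, , drop = FALSE], y[!l])
      if (cand < best) best <- cand
    }
  }
  best
}

training_sse <- function(tree, X, y) {
  sum((y - predict(tree, X))^2)
}

# Reproduce the internal pruning-fold assignment of fit_reptree().
reptree_prune_fold <- function(n, params) {
  set.seed(derive_seed(params$seed, "reptree_folds"))
  folds <- sample(rep_len(seq_len(params$n_pruning_folds), n))
  which(folds == 1L)
}
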