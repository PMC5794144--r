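#' Goodness-of-fit metrics for observed vs predicted water potential
#'
#' The primary R-squared is the squared Pearson correlation between observed
#' and predicted values, matching the observed-vs-predicted regression-plot
#' presentation; the coefficient-of-determination variant
#' `1 - SSE/SST` is reported alongside for transparency. RMSE is the root
#' mean squared prediction error in the target's units (MPa).
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return list `r2` (squared correlation), `r2_cod` (1 - SSE/SST), `rmse`.
#' @export
fit_metrics <- function(observed, predicted) {
  check_that(length(observed) == length(predicted) && length(observed) >= 2,
             "need >= 2 observed/predicted pairs")
  r <- stats::cor(observed, predicted)
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  list(r2 = if (is.na(r)) 0 else r^2,
       r2_cod = 1 - sse / sst,
       rmse = sqrt(mean((observed - predicted)^2)))
}

#' Build the balanced global dataset from both canopy sides
#'
#' Combines the side-specific tables into one dataset of the same size,
#' taking half of each (side, treatment, date) cell pseudorandomly so every
#' side, water regime and measurement day is equally represented — at the
#' default design, 6 of the 12 records in each of the 42 cells, i.e. 126 per
#' side.
#'
#' @param east,west per-side sample tables from [build_sample_table()].
#' @param seed integer seed for within-cell selection.
#' @return data.frame of `nrow(east)` records balanced across sides.
#' @export
make_global_dataset <- function(east, west, seed = 1L) {
  check_that(nrow(east) == nrow(west),
             "east and west must have the same number of records")
  both <- rbind(east, west)
  cell <- interaction(both$side, both$treatment, both$date, drop = TRUE)
  keep <- with_substream(seed, "global_cells", expr = {
    unlist(lapply(split(seq_len(nrow(both)), cell), function(idx) {
      k <- length(idx) %/% 2
      check_that(k >= 1 && length(idx) %% 2 == 0,
                 "cannot halve cell '%s' (size %d)",
                 as.character(cell[idx[1]]), length(idx))
      sort(sample(idx, k))
    }), use.names = FALSE)
  })
  out <- both[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Range- and date-stratified train/test split
#'
#' Implements the not-totally-random 80/20 division: the records holding the
#' global minimum and maximum stem water potential are forced into the test
#' set so it spans the whole observed range, and the remaining test slots are
#' filled with the same number of samples per measurement day (quota
#' remainders assigned to seeded date order). When `1/(1-ratio)` is a whole
#' number `k`, `n %% k` records are first excluded from both sets at random
#' so the split sizes are exact — for the default campaign this turns 252
#' records into exactly 200 train / 50 test.
#'
#' @param records sample table with columns `psi_stem` and `date`.
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @return object of class `split_plan`: `train`, `test`, `excluded` (integer
#'   row indices into `records`), `ratio`.
#' @export
stratified_split <- function(records, ratio = 0.8, seed = 1L) {
  n <- nrow(records)
  check_that(n >= 10, "need at least 10 records to split")
  check_that(ratio > 0 && ratio < 1, "ratio must be in (0, 1); got %g", ratio)
  dates <- sort(unique(records$date))

  with_substream(seed, "split", expr = {
    idx <- seq_len(n)
    excluded <- integer(0)
    inv <- 1 / (1 - ratio)
    if (abs(inv - round(inv)) < 1e-9) {
      surplus <- n %% as.integer(round(inv))
      if (surplus > 0) {
        excluded <- sort(sample(idx, surplus))
        idx <- setdiff(idx, excluded)
      }
    }
    m <- length(idx)
    n_test <- as.integer(round((1 - ratio) * m))
    check_that(n_test >= 1, "empty test set at ratio %g", ratio)

    psi <- records$psi_stem[idx]
    forced <- unique(c(idx[which.min(psi)], idx[which.max(psi)]))

    # per-date quotas: even base + remainder spread over a seeded date order
    base <- n_test %/% length(dates)
    extra_dates <- sample(dates)[seq_len(n_test %% length(dates))]
    quota <- stats::setNames(rep(base, length(dates)), dates)
    quota[as.character(extra_dates)] <- quota[as.character(extra_dates)] + 1L

    test <- forced
    for (d in dates) {
      pool <- setdiff(idx[records$date[idx] == d], test)
      need <- quota[[as.character(d)]] - sum(records$date[test] == d)
      check_that(need <= length(pool),
                 "date %s cannot fill its test quota", format(d))
      if (need > 0) test <- c(test, sample(pool, need))
    }
    test <- sort(test)
    train <- setdiff(idx, test)
    structure(list(train = train, test = test, excluded = excluded,
                   ratio = ratio),
              class = "split_plan")
  })
}

# Seeded k-fold assignment of m rows.
cv_folds <- function(m, k, seed) {
  check_that(m >= k, "fewer rows (%d) than folds (%d)", m, k)
  with_substream(seed, "cv_folds", expr = sample(rep_len(seq_len(k), m)))
}

#' Run the calibration / cross-validation / prediction protocol
#'
#' Fits the rotation forest and evaluates it three ways, as in the model
#' development protocol: calibration (fit on train, evaluate on train),
#' k-fold cross-validation (seeded random folds within train, held-out
#' predictions pooled), and external prediction (fit on train, evaluate on
#' test).
#'
#' @param records sample table (predictors per `feature_set` plus `psi_stem`).
#' @param split a [stratified_split()] plan over `records`.
#' @param forest_params a [rotation_forest_params()].
#' @param feature_set `"with_refs"` or `"without_refs"`.
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return object of class `evaluation_report`: `r2_*`/`rmse_*` for
#'   calibration, cv and prediction (plus `r2_cod_*`), `n_train`, `n_test`,
#'   `feature_set`, and `predictions` (per-sample observed/predicted for the
#'   cv and prediction stages).
#' @export
run_protocol <- function(records, split, forest_params = rotation_forest_params(),
                         feature_set = c("with_refs", "without_refs"),
                         n_folds = 10, seed = 1L) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(split, "split_plan"))
  cols <- feature_columns(feature_set)
  check_that(all(cols %in% names(records)),
             "records lack feature columns for %s", feature_set)
  X <- as.matrix(records[, cols, drop = FALSE])
  y <- records$psi_stem

  tr <- split$train
  te <- split$test

  model <- fit_rotation_forest(X[tr, , drop = FALSE], y[tr], forest_params)
  cal_pred <- as.numeric(predict(model, X[tr, , drop = FALSE]))
  cal <- fit_metrics(y[tr], cal_pred)

  folds <- cv_folds(length(tr), n_folds, seed)
  cv_pred <- numeric(length(tr))
  for (f in seq_len(n_folds)) {
    hold <- which(folds == f)
    check_that(length(hold) >= 1 && length(tr) - length(hold) >= 2,
               "fold %d too small", f)
    fp <- forest_params
    fp$seed <- derive_seed(seed, "cv_fit", f)
    m_f <- fit_rotation_forest(X[tr[-hold], , drop = FALSE], y[tr[-hold]], fp)
    cv_pred[hold] <- as.numeric(predict(m_f, X[tr[hold], , drop = FALSE]))
  }
  cv <- fit_metrics(y[tr], cv_pred)

  te_pred <- as.numeric(predict(model, X[te, , drop = FALSE]))
  pred <- fit_metrics(y[te], te_pred)

  structure(list(
    r2_calibration = cal$r2, rmse_calibration = cal$rmse,
    r2_cod_calibration = cal$r2_cod,
    r2_cv = cv$r2, rmse_cv = cv$rmse, r2_cod_cv = cv$r2_cod,
    r2_prediction = pred$r2, rmse_prediction = pred$rmse,
    r2_cod_prediction = pred$r2_cod,
    n_train = length(tr), n_test = length(te), feature_set = feature_set,
    predictions = list(
      cv = data.frame(observed = y[tr], predicted = cv_pred),
      prediction = data.frame(observed = y[te], predicted = te_pred)),
    model = model
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation report (%s; n_train=%d, n_test=%d)\n",
              x$feature_set, x$n_train, x$n_test))
  cat(sprintf("  calibration      R2 = %.3f  RMSE = %.3f MPa\n",
              x$r2_calibration, x$rmse_calibration))
  cat(sprintf("  cross-validation R2 = %.3f  RMSE = %.3f MPa\n",
              x$r2_cv, x$rmse_cv))
  cat(sprintf("  prediction       R2 = %.3f  RMSE = %.3f MPa\n",
              x$r2_prediction, x$rmse_prediction))
  invisible(x)
}

#' Test equality of observed-vs-predicted regression slopes
#'
#' Fits the least-squares line of observed on predicted values within each
#' group and tests slope equality with a pooled-residual-variance t statistic
#' on `n1 + n2 - 4` degrees of freedom (two-sided) — the comparison used to
#' ask whether the east- and west-side models share a calibration line.
#'
#' @param pairs_a,pairs_b data.frames with columns `observed`, `predicted`
#'   (>= 3 rows each).
#' @return list `t`, `p`, `df`, `slope_a`, `slope_b`.
#' @export
slope_equality_test <- function(pairs_a, pairs_b) {
  one <- function(d) {
    check_that(nrow(d) >= 3, "need >= 3 pairs per group")
    x <- d$predicted
    y <- d$observed
    sxx <- sum((x - mean(x))^2)
    check_that(sxx > 0, "zero predictor variance in a group")
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - b * mean(x)
    list(slope = b, sse = sum((y - a - b * x)^2), sxx = sxx, n = nrow(d))
  }
  fa <- one(pairs_a)
  fb <- one(pairs_b)
  df <- fa$n + fb$n - 4
  s2 <- (fa$sse + fb$sse) / df
  se <- sqrt(s2 * (1 / fa$sxx + 1 / fb$sxx))
  t <- if (se == 0) 0 else (fa$slope - fb$slope) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df,
       slope_a = fa$slope, slope_b = fb$slope)
}
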