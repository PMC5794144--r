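# Records with dummy features: enough structure for split/balance logic.
fake_records <- function(seed = 1, design = campaign_design()) {
  camp <- sample_campaign(design, seed = seed)
  tr <- camp$truth
  set.seed(derive_seed(seed, "fake_feats"))
  tr$air_temp <- rnorm(nrow(tr), 30, 3)
  tr$t_canopy_mean <- 25 + 8 * tr$true_cwsi + rnorm(nrow(tr), 0, 0.1)
  tr$t_canopy_median <- tr$t_canopy_mean + rnorm(nrow(tr), 0, 0.05)
  tr$t_canopy_sd <- abs(rnorm(nrow(tr), 1, 0.2))
  tr$cwsi <- tr$true_cwsi + rnorm(nrow(tr), 0, 0.01)
  tr$ig <- 1 / pmax(tr$cwsi, 1e-3) - 1
  tr
}

test_that("fit metrics match their definitions", {
  obs <- c(-1.2, -0.8, -1.5, -1.0, -1.8)
  pred <- c(-1.1, -0.9, -1.4, -1.2, -1.6)
  m <- fit_metrics(obs, pred)
  expect_equal(m$r2, cor(obs, pred)^2)
  expect_equal(m$rmse, sqrt(mean((obs - pred)^2)))
  expect_equal(m$r2_cod, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))

  perfect <- fit_metrics(obs, obs)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2_cod, 1)
})

test_that("the global dataset balances sides, regimes and dates", {
  recs <- fake_records(seed = 5)
  east <- recs[recs$side == "east", ]
  west <- recs[recs$side == "west", ]
  glob <- make_global_dataset(east, west, seed = 3)
  expect_identical(nrow(glob), 252L)
  expect_identical(as.vector(table(glob$side)), c(126L, 126L))
  cells <- table(glob$side, glob$treatment, glob$date)
  expect_true(all(cells == 6L))  # half of each 12-record cell

  # identical input sets: output is exactly half of each
  glob2 <- make_global_dataset(east, east, seed = 3)
  expect_identical(nrow(glob2), nrow(east))

  odd <- east[-1, ]  # one cell now has 11 records
  expect_error(make_global_dataset(odd, west[-1, ], seed = 3), "halve")
})

test_that("the stratified split produces the 200/50 shape", {
  recs <- fake_records(seed = 8)
  east <- recs[recs$side == "east", ]
  sp <- stratified_split(east, ratio = 0.8, seed = 4)
  expect_identical(length(sp$train), 200L)
  expect_identical(length(sp$test), 50L)
  expect_identical(length(sp$excluded), 2L)
  expect_length(intersect(sp$train, sp$test), 0)

  # per-date test counts even to within one
  per_date <- table(east$date[sp$test])
  expect_lte(max(per_date) - min(per_date), 1)

  expect_error(stratified_split(east, ratio = 1.0), "ratio")
})

test_that("the test set always spans the whole water potential range", {
  recs <- fake_records(seed = 2)
  east <- recs[recs$side == "east", ]
  for (s in 1:25) {
    sp <- stratified_split(east, seed = s)
    used <- c(sp$train, sp$test)
    expect_equal(min(east$psi_stem[sp$test]), min(east$psi_stem[used]))
    expect_equal(max(east$psi_stem[sp$test]), max(east$psi_stem[used]))
  }
})

test_that("splits are deterministic per seed", {
  east <- fake_records(seed = 3)
  east <- east[east$side == "east", ]
  expect_identical(stratified_split(east, seed = 7),
                   stratified_split(east, seed = 7))
  expect_false(identical(stratified_split(east, seed = 7)$test,
                         stratified_split(east, seed = 8)$test))
})

test_that("the protocol computes calibration, CV and prediction coherently", {
  recs <- fake_records(seed = 11)
  east <- recs[recs$side == "east", ]
  sp <- stratified_split(east, seed = 11)
  fp <- rotation_forest_params(n_trees = 3, seed = 11)
  rep <- run_protocol(east, sp, forest_params = fp, feature_set = "with_refs",
                      n_folds = 5, seed = 11)
  expect_identical(rep$n_train, 200L)
  expect_identical(rep$n_test, 50L)

  # RMSE(prediction) equals the brute-force recomputation on the test rows
  p <- rep$predictions$prediction
  expect_equal(rep$rmse_prediction,
               sqrt(mean((p$observed - p$predicted)^2)))
  expect_equal(p$observed, east$psi_stem[sp$test])

  # calibration should not trail cross-validation on signal-bearing data
  expect_gte(rep$r2_calibration, rep$r2_cv - 0.02)
  expect_true(all(c(rep$rmse_calibration, rep$rmse_cv, rep$rmse_prediction) >= 0))
})

test_that("slope equality testing behaves at its boundaries", {
  set.seed(40)
  x <- rnorm(30)
  a <- data.frame(predicted = x, observed = x + rnorm(30, 0, 0.1))
  same <- slope_equality_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # clearly different slopes, low noise
  x1 <- seq(-1, 1, length.out = 50)
  g1 <- data.frame(predicted = x1, observed = 1.0 * x1 + rnorm(50, 0, 0.02))
  g2 <- data.frame(predicted = x1, observed = 0.5 * x1 + rnorm(50, 0, 0.02))
  diff <- slope_equality_test(g1, g2)
  expect_lt(diff$p, 0.001)
  expect_equal(diff$df, 96)

  expect_error(slope_equality_test(a[1:2, ], a), "pairs")
  degen <- data.frame(predicted = rep(1, 5), observed = rnorm(5))
  expect_error(slope_equality_test(degen, a), "variance")
})

test_that("slope test agrees with the lm interaction oracle", {
  set.seed(50)
  for (i in 1:5) {
    g1 <- data.frame(predicted = rnorm(20), observed = rnorm(20))
    g2 <- data.frame(predicted = rnorm(25), observed = rnorm(25))
    ours <- slope_equality_test(g1, g2)
    both <- rbind(cbind(g1, grp = 0), cbind(g2, grp = 1))
    fit <- lm(observed ~ predicted * grp, data = both)
    p_lm <- summary(fit)$coefficients["predicted:grp", "Pr(>|t|)"]
    t_lm <- summary(fit)$coefficients["predicted:grp", "t value"]
    expect_equal(abs(ours$t), abs(t_lm), tolerance = 1e-8)
    expect_equal(ours$p, p_lm, tolerance = 1e-8)
  }
})
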