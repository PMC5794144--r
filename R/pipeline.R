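#' Run configuration tying all pipeline stages together
#'
#' One object holds everything needed to reproduce a full run: the campaign
#' design, camera and traverse geometry, generator and scene parameters, the
#' ROI, the feature sets to evaluate, the forest hyperparameters, the split
#' ratio and fold count, and the single master seed from which every
#' stochastic stage derives its substream.
#'
#' @param design a [campaign_design()].
#' @param camera a [camera_model()].
#' @param traverse a [traverse_spec()].
#' @param generator a [generator_params()].
#' @param scene a [scene_params()].
#' @param roi a [roi_spec()].
#' @param feature_sets character subset of `c("with_refs", "without_refs")`.
#' @param forest a [rotation_forest_params()].
#' @param split_ratio training fraction.
#' @param n_folds cross-validation folds.
#' @param seed master integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(design = campaign_design(), camera = camera_model(),
                       traverse = traverse_spec(),
                       generator = generator_params(), scene = scene_params(),
                       roi = roi_spec(),
                       feature_sets = c("with_refs", "without_refs"),
                       forest = rotation_forest_params(), split_ratio = 0.8,
                       n_folds = 10, seed = 1L) {
  check_that(all(feature_sets %in% c("with_refs", "without_refs")) &&
               length(feature_sets) >= 1, "invalid feature_sets")
  structure(list(design = design, camera = camera, traverse = traverse,
                 generator = generator, scene = scene, roi = roi,
                 feature_sets = feature_sets, forest = forest,
                 split_ratio = split_ratio, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "run_config")
}

# Constructor registry used to round-trip configs through YAML.
config_constructors <- function() {
  list(design = campaign_design, camera = camera_model,
       traverse = traverse_spec, generator = generator_params,
       scene = scene_params, roi = roi_spec, forest = rotation_forest_params)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Save / load a run configuration as YAML
#'
#' The YAML round-trip is lossless for every parameter the constructors
#' accept; unknown keys are rejected so typos fail loudly.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `save_run_config` returns the path invisibly; `load_run_config`
#'   returns a `run_config`.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(strip_classes(unclass(config)), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ctors <- config_constructors()
  known <- c(names(ctors), "feature_sets", "split_ratio", "n_folds", "seed")
  bad <- setdiff(names(raw), known)
  check_that(length(bad) == 0, "unknown config key(s): %s",
             paste(bad, collapse = ", "))
  args <- list()
  for (nm in names(raw)) {
    if (nm %in% names(ctors)) {
      sub <- raw[[nm]]
      if (nm == "forest" && !is.null(sub$tree_params)) {
        sub$tree_params <- do.call(reptree_params, sub$tree_params)
      }
      if (nm == "scene" || nm == "generator") {
        sub <- lapply(sub, function(v) if (is.list(v)) unlist(v) else v)
      }
      if (nm == "camera" && !is.null(sub$resolution)) {
        sub$resolution <- unlist(sub$resolution)
      }
      if (nm == "design") {
        sub <- lapply(sub, function(v) if (is.list(v)) unlist(v) else v)
      }
      if (nm == "roi" && length(sub) > 0) {
        sub <- sub[!vapply(sub, is.null, logical(1))]
      }
      args[[nm]] <- do.call(ctors[[nm]], sub)
    } else {
      args[[nm]] <- if (is.list(raw[[nm]])) unlist(raw[[nm]]) else raw[[nm]]
    }
  }
  do.call(run_config, args)
}

# Render only the selected frames of every measured vine and return them as
# the named list build_sample_table() expects.
render_selected_frames <- function(campaign, config) {
  total <- frames_per_replication(config$camera, config$traverse)
  sel <- select_frames(total, config$camera, config$traverse)
  groups <- partition_frames(length(sel), config$design$vines_per_replication)
  frames <- list()
  for (i in seq_len(nrow(campaign$truth))) {
    tr <- campaign$truth[i, ]
    w <- campaign$weather[campaign$weather$date == tr$date, ]
    idx <- sel[groups[[tr$vine]]]
    frames[[vine_key(tr)]] <- render_frame_sequence(
      tr, w, camera = config$camera, scene = config$scene,
      traverse = config$traverse, n_frames = total, indices = idx,
      seed = config$seed)
  }
  frames
}

#' Run the whole pipeline end to end
#'
#' Samples a synthetic campaign, renders the selected thermal frames for
#' every measured vine, extracts per-vine features, assembles the
#' side-specific and balanced global datasets, and runs the stratified
#' split + calibration / cross-validation / prediction protocol for every
#' dataset and feature set — at the defaults, 3 datasets (east, west, global)
#' x 2 feature sets = 6 evaluation reports.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes `weather.csv`,
#'   `truth.csv`, one `features_<set>_<dataset>.csv` per combination,
#'   `report.csv`, `predictions.csv` and `config.yaml` (stamped with the
#'   seed and a config hash).
#' @return list: `reports` (named `"<dataset>.<feature_set>"`),
#'   `report_table` (one row per dataset x feature set x stage), `features`,
#'   `campaign`, `config`.
#' @export
run_end_to_end <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  check_that(scene_coverage(config$camera)[["width_m"]] > 0,
             "stage geometry: zero scene coverage")
  sides <- config$design$sides
  check_that(length(sides) == 2, "end-to-end run expects two canopy sides")

  campaign <- tryCatch(
    sample_campaign(config$design, config$generator, config$seed),
    error = function(e) stop_domain("stage synth: %s", conditionMessage(e)))
  frames <- tryCatch(render_selected_frames(campaign, config),
    error = function(e) stop_domain("stage render: %s", conditionMessage(e)))

  datasets <- list()
  features <- list()
  for (fs in config$feature_sets) {
    tabs <- lapply(sides, function(s) {
      tr <- campaign$truth[campaign$truth$side == s, ]
      build_sample_table(frames, campaign$weather, tr, feature_set = fs,
                         roi = config$roi)
    })
    names(tabs) <- sides
    tabs$global <- make_global_dataset(tabs[[sides[1]]], tabs[[sides[2]]],
                                       seed = derive_seed(config$seed, "global", fs))
    features[[fs]] <- tabs
    for (ds in names(tabs)) {
      datasets[[paste(ds, fs, sep = ".")]] <- tabs[[ds]]
    }
  }

  reports <- list()
  rows <- list()
  for (key in names(datasets)) {
    recs <- datasets[[key]]
    sp <- stratified_split(recs, ratio = config$split_ratio,
                           seed = derive_seed(config$seed, "split", key))
    fs <- sub("^.*\\.", "", key)
    rep <- tryCatch(
      run_protocol(recs, sp, forest_params = config$forest, feature_set = fs,
                   n_folds = config$n_folds,
                   seed = derive_seed(config$seed, "protocol", key)),
      error = function(e) stop_domain("stage evaluate [%s]: %s", key,
                                      conditionMessage(e)))
    reports[[key]] <- rep
    ds <- sub("\\..*$", "", key)
    rows[[key]] <- data.frame(
      dataset = ds, feature_set = fs,
      stage = c("calibration", "cv", "prediction"),
      r2 = c(rep$r2_calibration, rep$r2_cv, rep$r2_prediction),
      r2_cod = c(rep$r2_cod_calibration, rep$r2_cod_cv, rep$r2_cod_prediction),
      rmse = c(rep$rmse_calibration, rep$rmse_cv, rep$rmse_prediction),
      n_train = rep$n_train, n_test = rep$n_test)
  }
  report_table <- do.call(rbind, rows)
  rownames(report_table) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_campaign(campaign, out_dir)
    for (fs in names(features)) {
      for (ds in names(features[[fs]])) {
        utils::write.csv(features[[fs]][[ds]],
                         file.path(out_dir, sprintf("features_%s_%s.csv", fs, ds)),
                         row.names = FALSE)
      }
    }
    fmt <- report_table
    for (cl in c("r2", "r2_cod", "rmse")) fmt[[cl]] <- sprintf("%.6f", fmt[[cl]])
    utils::write.csv(fmt, file.path(out_dir, "report.csv"), row.names = FALSE)
    preds <- do.call(rbind, lapply(names(reports), function(key) {
      p <- reports[[key]]$predictions$prediction
      cbind(data.frame(dataset_feature_set = key, stage = "prediction"), p)
    }))
    preds$observed <- sprintf("%.6f", preds$observed)
    preds$predicted <- sprintf("%.6f", preds$predicted)
    utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    save_run_config(config, file.path(out_dir, "config.yaml"))
    stamp <- data.frame(
      seed = config$seed,
      config_hash = sprintf("%08x", derive_seed(config$seed, yaml::as.yaml(
        strip_classes(unclass(config))))))
    utils::write.csv(stamp, file.path(out_dir, "run_stamp.csv"),
                     row.names = FALSE)
  }

  list(reports = reports, report_table = report_table, features = features,
       campaign = campaign, config = config)
}

#' Print the full acquisition and design derivation table
#'
#' Recomputes and prints the audit chain for a configuration: frame ground
#' coverage, frames per replication, non-overlap stride, subsampled and
#' retained frame counts, measurements per day and per campaign side.
#'
#' @param config a [run_config()].
#' @return invisibly, a data.frame of `quantity` / `value`.
#' @export
explain_run <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  check_that(scene_coverage(config$camera)[["width_m"]] > 0 &&
               scene_coverage(config$camera)[["height_m"]] > 0,
             "zero field of view: nothing to derive")
  geo <- geometry_table(config$camera, config$traverse)
  per_day <- length(config$design$treatments) * config$design$n_blocks *
    config$design$vines_per_replication
  tab <- rbind(geo, data.frame(
    quantity = c("measurements_per_day", "samples_per_side"),
    value = c(per_day, samples_per_side(config$design))))
  cat(sprintf("%-24s %10s\n", "quantity", "value"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%-24s %10g\n", tab$quantity[i], tab$value[i]))
  }
  invisible(tab)
}
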