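#' Region of interest: the central horizontal band of a frame
#'
#' The area of interest excludes sky at the top and the soil/fruiting zone at
#' the bottom of a sideways canopy frame. By default it is the vertically
#' centred 135-row band of a 256-row image (rows 61-195, all columns), i.e.
#' a 320 x 135 sub-image at the default resolution.
#'
#' @param row_start,row_end 1-based inclusive row range. `NULL` picks the
#'   centred band of `height` rows at crop time.
#' @param height band height in rows, used when `row_start` is `NULL`.
#' @return an object of class `roi`.
#' @export
roi_spec <- function(row_start = NULL, row_end = NULL, height = 135) {
  if (!is.null(row_start)) {
    check_that(!is.null(row_end) && row_end >= row_start && row_start >= 1,
               "row_end must be >= row_start >= 1")
  } else {
    check_that(height >= 1, "roi height must be >= 1")
  }
  structure(list(row_start = row_start, row_end = row_end, height = height),
            class = "roi")
}

#' Crop a frame to its region of interest
#'
#' Pure index selection: no temperature is modified. A `NULL`-anchored ROI is
#' resolved to the centred band, biased one row up when the margin is odd.
#'
#' @param frame numeric matrix (rows = image rows).
#' @param roi a [roi_spec()].
#' @return the sub-matrix.
#' @export
crop_roi <- function(frame, roi = roi_spec()) {
  stopifnot(is.matrix(frame), inherits(roi, "roi"))
  h <- nrow(frame)
  if (is.null(roi$row_start)) {
    check_that(roi$height <= h, "roi height %d exceeds frame height %d",
               roi$height, h)
    top <- (h - roi$height) %/% 2
    rs <- top + 1L
    re <- top + roi$height
  } else {
    rs <- roi$row_start
    re <- roi$row_end
    check_that(re <= h, "roi rows [%d, %d] out of bounds for height %d",
               rs, re, h)
  }
  frame[rs:re, , drop = FALSE]
}

#' Per-day wet and dry reference temperatures
#'
#' Temperatures of the evaposensor's artificial leaves: a continuously wetted
#' one (lower bound of attainable canopy temperature) and a dry one (upper
#' bound).
#'
#' @param t_wet,t_dry reference temperatures, degrees C; `t_dry > t_wet`.
#' @param date optional date label.
#' @return an object of class `reference_temperatures`.
#' @export
reference_temperatures <- function(t_wet, t_dry, date = NA) {
  check_that(is.finite(t_wet) && is.finite(t_dry) && t_dry > t_wet,
             "t_dry (%s) must exceed t_wet (%s)", format(t_dry), format(t_wet))
  structure(list(t_wet = t_wet, t_dry = t_dry, date = date),
            class = "reference_temperatures")
}

#' Mask pixels outside the wet-dry reference range
#'
#' Pixels outside the closed interval `[t_wet, t_dry]` are set to `NA` (the
#' interval is closed so reference-equal pixels survive and the CWSI
#' boundaries 0 and 1 stay attainable). Masks are carried as `NA`, never as
#' sentinel temperatures.
#'
#' @param pixels numeric matrix, degrees C.
#' @param refs a [reference_temperatures()].
#' @return the matrix with out-of-range pixels `NA`; attribute `n_retained`
#'   counts survivors. Zero survivors are allowed here but flagged by
#'   [frame_statistics()] downstream.
#' @export
segment_by_references <- function(pixels, refs) {
  stopifnot(inherits(refs, "reference_temperatures"))
  out <- pixels
  out[out < refs$t_wet | out > refs$t_dry] <- NA_real_
  attr(out, "n_retained") <- sum(!is.na(out))
  out
}

#' Summary statistics of a (possibly masked) pixel matrix
#'
#' Mean, median and sample (n-1) standard deviation over unmasked pixels —
#' the per-frame statistics feeding the prediction models. The mean is the
#' canopy temperature entering the thermal indices when segmentation was
#' applied.
#'
#' @param pixels numeric matrix; `NA` marks masked pixels.
#' @return list `t_mean`, `t_median`, `t_sd`, `n_pixels_used`.
#' @export
frame_statistics <- function(pixels) {
  v <- pixels[!is.na(pixels)]
  check_that(length(v) >= 1, "no unmasked pixels: empty segmentation")
  list(t_mean = mean(v), t_median = stats::median(v),
       t_sd = if (length(v) > 1) stats::sd(v) else 0,
       n_pixels_used = length(v))
}

#' Crop water stress index
#'
#' `CWSI = (T_canopy - T_wet) / (T_dry - T_wet)`: 0 when the canopy sits at
#' the wet reference (full transpiration), 1 at the dry reference (none). It
#' lies in \[0, 1\] exactly when `T_canopy` lies between the references.
#'
#' @param t_canopy canopy temperature, degrees C.
#' @param refs a [reference_temperatures()].
#' @return dimensionless index.
#' @export
cwsi <- function(t_canopy, refs) {
  stopifnot(inherits(refs, "reference_temperatures"))
  (t_canopy - refs$t_wet) / (refs$t_dry - refs$t_wet)
}

#' Conductance index
#'
#' `Ig = (T_dry - T_canopy) / (T_canopy - T_wet)`, proportional to stomatal
#' conductance; algebraically `Ig = 1/CWSI - 1` wherever both are defined.
#' Undefined at `T_canopy = T_wet` (the non-transpiration-limited edge).
#'
#' @inheritParams cwsi
#' @return dimensionless index.
#' @export
ig <- function(t_canopy, refs) {
  stopifnot(inherits(refs, "reference_temperatures"))
  check_that(all(t_canopy != refs$t_wet),
             "Ig undefined at t_canopy == t_wet")
  (refs$t_dry - t_canopy) / (t_canopy - refs$t_wet)
}

# Partition n frames into k contiguous groups of near-equal size, centred:
# group boundaries at round(n * (1:k) / k). For 14 frames and 3 vine groups
# this gives sizes 5, 4, 5, mirroring the 3 groups of 5 monitored plants.
partition_frames <- function(n, k) {
  bounds <- round_half_up(n * seq_len(k) / k)
  starts <- c(0, bounds[-k]) + 1
  mapply(function(s, e) if (s <= e) seq(s, e) else integer(0),
         starts, bounds, SIMPLIFY = FALSE)
}

# Features of one vine: average of per-frame statistics over its frame group.
vine_features <- function(frames, refs, feature_set, roi) {
  per_frame <- lapply(frames, function(px) {
    cropped <- crop_roi(px, roi)
    if (feature_set == "with_refs") {
      seg <- segment_by_references(cropped, refs)
      if (attr(seg, "n_retained") == 0) return(NULL)
      st <- frame_statistics(seg)
      st$cwsi <- cwsi(st$t_mean, refs)
      st$ig <- ig(st$t_mean, refs)
      st
    } else {
      frame_statistics(cropped)
    }
  })
  per_frame <- Filter(Negate(is.null), per_frame)
  if (length(per_frame) == 0) return(NULL)
  agg <- function(field) mean(vapply(per_frame, `[[`, numeric(1), field))
  out <- list(t_canopy_mean = agg("t_mean"), t_canopy_median = agg("t_median"),
              t_canopy_sd = agg("t_sd"))
  if (feature_set == "with_refs") {
    out$cwsi <- agg("cwsi")
    out$ig <- agg("ig")
  }
  out
}

#' Build the per-vine sample table from frames, weather and ground truth
#'
#' Assembles one training row per measured vine. The vine's retained frames
#' are split into contiguous groups (one per vine, mirroring the monitored
#' plant groups along the row); features are per-frame statistics averaged
#' over the vine's group. Two feature sets exist:
#' \describe{
#'   \item{`with_refs`}{air temperature + mean/median/SD of the segmented ROI
#'     plus CWSI and Ig computed from the segmented mean (6 predictors).}
#'   \item{`without_refs`}{air temperature + mean/median/SD of the raw,
#'     unsegmented ROI (4 predictors); reference temperatures are never
#'     touched at any stage.}
#' }
#'
#' @param frames named list: `frames[[vine_key]]` is the list of that vine's
#'   frames; keys built by [vine_key()].
#' @param weather `weather` data.frame from [sample_campaign()].
#' @param truth `truth` data.frame from [sample_campaign()].
#' @param feature_set `"with_refs"` or `"without_refs"`.
#' @param roi a [roi_spec()].
#' @return data.frame: strata columns (`date`, `treatment`, `block`, `side`,
#'   `vine`), predictors (`air_temp`, `t_canopy_mean`, `t_canopy_median`,
#'   `t_canopy_sd`, and for `with_refs` `cwsi`, `ig`) and target `psi_stem`.
#'   Vines whose frames were all empty after segmentation are dropped with a
#'   warning.
#' @export
build_sample_table <- function(frames, weather, truth,
                               feature_set = c("with_refs", "without_refs"),
                               roi = roi_spec()) {
  feature_set <- match.arg(feature_set)
  rows <- vector("list", nrow(truth))
  dropped <- character(0)
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    key <- vine_key(tr)
    fr <- frames[[key]]
    check_that(!is.null(fr) && length(fr) >= 1,
               "no frames for vine %s", key)
    w <- weather[weather$date == tr$date, ]
    refs <- reference_temperatures(w$t_wet, w$t_dry, w$date)
    feat <- vine_features(fr, refs, feature_set, roi)
    if (is.null(feat)) {
      dropped <- c(dropped, key)
      next
    }
    rows[[i]] <- cbind(
      tr[c("date", "treatment", "block", "side", "vine")],
      data.frame(air_temp = w$air_temp), as.data.frame(feat),
      data.frame(psi_stem = tr$psi_stem))
  }
  if (length(dropped) > 0) {
    warning(sprintf("%d vine(s) dropped (empty segmentation): %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Key identifying one measured vine
#'
#' @param truth_row one-row slice of the `truth` data.frame.
#' @return character key `d<date>_<treatment>_b<block>_<side>_v<vine>`.
#' @export
vine_key <- function(truth_row) {
  sprintf("d%d_%s_b%d_%s_v%d", truth_row$date, truth_row$treatment,
          truth_row$block, truth_row$side, truth_row$vine)
}

#' Predictor column names of a feature set
#'
#' @param feature_set `"with_refs"` or `"without_refs"`.
#' @return character vector of predictor names.
#' @export
feature_columns <- function(feature_set = c("with_refs", "without_refs")) {
  feature_set <- match.arg(feature_set)
  base <- c("air_temp", "t_canopy_mean", "t_canopy_median", "t_canopy_sd")
  if (feature_set == "with_refs") c(base, "cwsi", "ig") else base
}
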