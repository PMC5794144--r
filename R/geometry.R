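#' Camera model for on-the-go thermal acquisition
#'
#' Describes the thermal camera as mounted on the vehicle: frame rate, the
#' horizontal and vertical fields of view, the distance from the lens to the
#' canopy, the mounting height, and the sensor resolution. Defaults correspond
#' to an uncooled longwave camera recording 320x256 frames at 60 FPS, aimed
#' sideways at a canopy 1.2 m away with 48 x 39 degree fields of view.
#'
#' @param fps frames per second (> 0).
#' @param fov_h,fov_v horizontal / vertical field of view, degrees in (0, 180).
#'   A zero FOV is accepted by [scene_coverage()] (it yields zero coverage) but
#'   rejected by pipeline validation.
#' @param distance_m distance from camera to canopy, metres (> 0).
#' @param height_m mounting height above ground, metres.
#' @param resolution integer vector `c(width, height)` in pixels.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(fps = 60, fov_h = 48, fov_v = 39, distance_m = 1.2,
                         height_m = 1.0, resolution = c(320L, 256L)) {
  check_that(fps > 0, "fps must be > 0 (got %g)", fps)
  check_that(fov_h >= 0 && fov_h < 180, "fov_h must be in [0, 180) degrees")
  check_that(fov_v >= 0 && fov_v < 180, "fov_v must be in [0, 180) degrees")
  check_that(distance_m > 0, "distance_m must be > 0")
  check_that(length(resolution) == 2 && all(resolution >= 1),
             "resolution must be c(width, height) with positive entries")
  structure(
    list(fps = fps, fov_h = fov_h, fov_v = fov_v, distance_m = distance_m,
         height_m = height_m, resolution = as.integer(resolution)),
    class = "camera_model"
  )
}

#' Traverse specification for one treatment replication
#'
#' @param speed_kmh vehicle speed along the row, km/h (> 0).
#' @param replication_length_m length of one treatment replication, metres.
#' @param monitored_length_m length of the monitored middle section (the
#'   plants on which water status is actually measured); must not exceed
#'   `replication_length_m`.
#' @return an object of class `traverse_spec`.
#' @export
traverse_spec <- function(speed_kmh = 5, replication_length_m = 25,
                          monitored_length_m = 15) {
  check_that(speed_kmh > 0, "speed_kmh must be > 0")
  check_that(replication_length_m > 0, "replication_length_m must be > 0")
  check_that(monitored_length_m > 0 &&
               monitored_length_m <= replication_length_m,
             "monitored_length_m must be in (0, replication_length_m]")
  structure(
    list(speed_kmh = speed_kmh,
         replication_length_m = replication_length_m,
         monitored_length_m = monitored_length_m),
    class = "traverse_spec"
  )
}

#' Ground footprint of one frame
#'
#' Width and height of the canopy scene covered by a single frame, from the
#' pinhole relation `2 * distance * tan(fov / 2)`.
#'
#' @param camera a [camera_model()].
#' @return named numeric vector `c(width_m, height_m)`.
#' @export
scene_coverage <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  w <- 2 * camera$distance_m * tan(camera$fov_h / 2 * pi / 180)
  h <- 2 * camera$distance_m * tan(camera$fov_v / 2 * pi / 180)
  c(width_m = w, height_m = h)
}

#' Number of frames recorded while traversing one replication
#'
#' `round(length / speed * fps)` with speed converted to m/s; rounding is half
#' away from zero.
#'
#' @param camera a [camera_model()].
#' @param traverse a [traverse_spec()].
#' @return integer frame count.
#' @export
frames_per_replication <- function(camera, traverse) {
  stopifnot(inherits(camera, "camera_model"), inherits(traverse, "traverse_spec"))
  speed_ms <- traverse$speed_kmh / 3.6
  as.integer(round_half_up(traverse$replication_length_m / speed_ms * camera$fps))
}

#' Subsampling stride yielding laterally non-overlapping frames
#'
#' With `n` frames covering a replication of length `L` and each frame showing
#' a strip of width `w`, only one frame in `round(n / (L / w))` shows a scene
#' disjoint from the previous retained one.
#'
#' @inheritParams frames_per_replication
#' @return integer stride. If a single frame already covers the whole
#'   replication, the stride equals the total frame count.
#' @export
nonoverlap_stride <- function(camera, traverse) {
  total <- frames_per_replication(camera, traverse)
  w <- scene_coverage(camera)[["width_m"]]
  check_that(w > 0, "frame width is zero: cannot compute a stride")
  if (w >= traverse$replication_length_m) return(total)
  as.integer(round_half_up(total / (traverse$replication_length_m / w)))
}

#' Select the non-overlapping middle frames of a recording
#'
#' Subsamples every stride-th frame (giving `round(L / w)` frames for
#' replication length `L` and frame width `w`), then keeps the centred block
#' of `floor(monitored_length / w)` frames covering the monitored middle
#' plants. When the number of frames to drop is odd, the extra frame is
#' dropped at the end of travel.
#'
#' @param total_frames number of frames in the recording.
#' @param camera a [camera_model()].
#' @param traverse a [traverse_spec()].
#' @return strictly increasing 0-based frame indices in `[0, total_frames)`.
#' @export
select_frames <- function(total_frames, camera, traverse) {
  check_that(total_frames >= 1, "total_frames must be >= 1")
  stride <- nonoverlap_stride(camera, traverse)
  w <- scene_coverage(camera)[["width_m"]]
  n_sub <- if (w >= traverse$replication_length_m) {
    1L
  } else {
    as.integer(round_half_up(traverse$replication_length_m / w))
  }
  sub <- seq(0L, by = stride, length.out = n_sub)
  sub <- sub[sub < total_frames]
  n_keep <- max(1L, as.integer(floor(traverse$monitored_length_m / w)))
  if (n_keep >= length(sub)) {
    if (n_keep > length(sub)) {
      warning(sprintf(
        "monitored block (%d frames) exceeds the subsample (%d frames); returning all",
        n_keep, length(sub)), call. = FALSE)
    }
    return(as.integer(sub))
  }
  drop <- length(sub) - n_keep
  drop_head <- drop %/% 2          # odd surplus: extra frame dropped at the end
  as.integer(sub[(drop_head + 1):(drop_head + n_keep)])
}

#' Print the acquisition-geometry derivation table
#'
#' Recomputes, for a given camera and traverse, the whole chain: scene
#' coverage, frames per replication, non-overlap stride, subsampled frame
#' count and retained middle frames.
#'
#' @inheritParams frames_per_replication
#' @return invisibly, a data.frame of the derived quantities.
#' @export
geometry_table <- function(camera = camera_model(), traverse = traverse_spec()) {
  cov <- scene_coverage(camera)
  check_that(cov[["width_m"]] > 0, "zero field of view: no ground coverage")
  total <- frames_per_replication(camera, traverse)
  stride <- nonoverlap_stride(camera, traverse)
  sel <- select_frames(total, camera, traverse)
  n_sub <- as.integer(round_half_up(
    traverse$replication_length_m / cov[["width_m"]]))
  tab <- data.frame(
    quantity = c("scene_width_m", "scene_height_m", "frames_per_replication",
                 "nonoverlap_stride", "subsampled_frames", "retained_frames"),
    value = c(round(cov[["width_m"]], 2), round(cov[["height_m"]], 2),
              total, stride, n_sub, length(sel))
  )
  invisible(tab)
}
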