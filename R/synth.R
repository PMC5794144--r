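#' Vineyard campaign design
#'
#' The layout of the measurement campaign: a randomized complete block design
#' with three irrigation regimes (T0 full, T1 moderate, T2 none) replicated in
#' four blocks, recorded on both canopy sides over several weekly measurement
#' dates. Each replication holds 25 plants over ~25 m of row; only the middle
#' 15 are monitored and one vine per group of five is measured, giving three
#' water-status measurements per replication. At the defaults this yields
#' 3 treatments x 4 blocks x 3 vines = 36 measurements per day and
#' 7 x 36 = 252 per campaign side.
#'
#' @param n_dates number of measurement dates (weekly; default 7).
#' @param treatments labels of the irrigation regimes, ordered from wettest to
#'   driest.
#' @param n_blocks number of replication blocks.
#' @param sides canopy sides recorded.
#' @param vines_per_replication measured vines per replication.
#' @param plants_per_replication total plants per replication (middle 15 of 25
#'   monitored at defaults; informational).
#' @param row_length_m replication row length, metres.
#' @return an object of class `campaign_design`.
#' @export
campaign_design <- function(n_dates = 7, treatments = c("T0", "T1", "T2"),
                            n_blocks = 4, sides = c("east", "west"),
                            vines_per_replication = 3,
                            plants_per_replication = 25, row_length_m = 25) {
  check_that(n_dates >= 1 && n_blocks >= 1 && vines_per_replication >= 1,
             "all design counts must be strictly positive")
  check_that(length(treatments) >= 1, "at least one treatment required")
  check_that(length(sides) >= 1, "at least one side required")
  structure(
    list(n_dates = as.integer(n_dates), treatments = treatments,
         n_blocks = as.integer(n_blocks), sides = sides,
         vines_per_replication = as.integer(vines_per_replication),
         plants_per_replication = as.integer(plants_per_replication),
         row_length_m = row_length_m),
    class = "campaign_design"
  )
}

#' Number of water-status samples per campaign side
#'
#' @param design a [campaign_design()].
#' @return integer: `n_dates * n_treatments * n_blocks * vines_per_replication`.
#' @export
samples_per_side <- function(design) {
  stopifnot(inherits(design, "campaign_design"))
  design$n_dates * length(design$treatments) * design$n_blocks *
    design$vines_per_replication
}

#' Vapour pressure deficit from air temperature and relative humidity
#'
#' Uses the Tetens saturation vapour pressure over water,
#' `e_s = 0.6108 * exp(17.27 * T / (T + 237.3))` kPa, so that
#' `VPD = e_s(T) * (1 - RH/100)`.
#'
#' @param air_temp air temperature, degrees C.
#' @param relative_humidity relative humidity, percent in \[0, 100\].
#' @return vapour pressure deficit, kPa (non-negative).
#' @export
vpd_from_weather <- function(air_temp, relative_humidity) {
  check_that(all(relative_humidity >= 0 & relative_humidity <= 100),
             "relative_humidity must be within [0, 100]")
  es <- 0.6108 * exp(17.27 * air_temp / (air_temp + 237.3))
  es * (1 - relative_humidity / 100)
}

#' Generator parameters for the synthetic campaign
#'
#' The stated world the generator emulates. Stem water potential is linked to
#' a latent per-vine crop water stress index by
#' `psi = intercept + slope * cwsi + side effect + Gaussian noise`, clamped to
#' `psi_range`; with the defaults `intercept = -0.40` and `slope = -1.65` the
#' index range \[0, 1\] maps onto the observed range \[-2.05, -0.40\] MPa. The
#' latent index is Beta-distributed with treatment-specific means spread
#' `cwsi_treatment_spread` around a centre chosen so the marginal mean of psi
#' equals `psi_mean_target`; the unirrigated regime drifts drier over the
#' season via `cwsi_date_slopes`. The noise SD is set so the marginal SD of
#' psi is close to 0.298 MPa.
#'
#' @param psi_intercept,psi_slope linear link from index to psi (MPa).
#' @param psi_mean_target marginal mean of psi the generator is calibrated to
#'   (MPa).
#' @param psi_noise_sd residual SD around the link (MPa).
#' @param psi_range attainable psi interval (MPa); draws are clamped to it.
#' @param side_effect_mpa additive effect: + for the first side, - for the
#'   second.
#' @param cwsi_treatment_spread half-spread of treatment index means around
#'   the calibrated centre (wettest = centre - spread, driest = centre +
#'   spread; intermediate regimes interpolated).
#' @param cwsi_date_slopes per-treatment seasonal drift of the index mean over
#'   the centred date covariate in \[-0.5, 0.5\].
#' @param cwsi_precision Beta precision (shape1 + shape2) of the index.
#' @param air_temp_mean,air_temp_sd daily air temperature model, degrees C.
#' @param rh_mean,rh_sd,rh_range daily relative humidity model, percent.
#' @param irradiance_mean,irradiance_sd daily solar irradiance model, W/m^2.
#' @param t_wet_offset,t_dry_offset mean offsets of the wet/dry reference
#'   temperatures from air temperature, degrees C.
#' @param ref_noise_sd day-to-day SD of the reference offsets, degrees C.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(psi_intercept = -0.40, psi_slope = -1.65,
                             psi_mean_target = -1.23, psi_noise_sd = 0.16,
                             psi_range = c(-2.05, -0.40),
                             side_effect_mpa = 0.01,
                             cwsi_treatment_spread = 0.14,
                             cwsi_date_slopes = c(0, 0.1, 0.2),
                             cwsi_precision = 30,
                             air_temp_mean = 30, air_temp_sd = 3,
                             rh_mean = 40, rh_sd = 8, rh_range = c(15, 80),
                             irradiance_mean = 850, irradiance_sd = 80,
                             t_wet_offset = -3, t_dry_offset = 6,
                             ref_noise_sd = 0.5) {
  check_that(psi_slope < 0, "psi_slope must be negative (hotter canopy = more stress)")
  check_that(psi_noise_sd >= 0 && cwsi_precision > 0, "invalid noise parameters")
  check_that(t_dry_offset > t_wet_offset, "t_dry offset must exceed t_wet offset")
  structure(as.list(environment()), class = "generator_params")
}

# Treatment-by-date mean of the latent index, clamped to (0, 1).
cwsi_mean_grid <- function(design, params) {
  k <- length(design$treatments)
  centre <- (params$psi_mean_target - params$psi_intercept) / params$psi_slope
  base <- if (k == 1) centre else
    centre + seq(-1, 1, length.out = k) * params$cwsi_treatment_spread
  slopes <- rep_len(params$cwsi_date_slopes, k)
  x <- if (design$n_dates == 1) 0 else
    (seq_len(design$n_dates) - (design$n_dates + 1) / 2) / (design$n_dates - 1)
  mu <- outer(x, slopes) + matrix(base, design$n_dates, k, byrow = TRUE)
  pmin(pmax(mu, 0.02), 0.98)  # rows = dates, cols = treatments
}

#' Sample a synthetic campaign: daily weather and ground-truth water status
#'
#' Draws one weather record per measurement date (air temperature, relative
#' humidity, VPD, irradiance, and the wet/dry evaposensor reference
#' temperatures) and one ground-truth record per measured vine (latent crop
#' water stress index and stem water potential). All randomness flows from
#' `seed` through named substreams, so results are bit-identical per seed.
#'
#' @param design a [campaign_design()].
#' @param params a [generator_params()].
#' @param seed master integer seed.
#' @return list with data.frames `weather` (one row per date: `date`,
#'   `air_temp`, `rh`, `vpd`, `irradiance`, `t_wet`, `t_dry`) and `truth`
#'   (one row per date x treatment x block x side x vine: adds `psi_stem`
#'   MPa and `true_cwsi`).
#' @export
sample_campaign <- function(design = campaign_design(),
                            params = generator_params(), seed = 1L) {
  stopifnot(inherits(design, "campaign_design"),
            inherits(params, "generator_params"))

  weather <- with_substream(seed, "weather", expr = {
    n <- design$n_dates
    air <- stats::rnorm(n, params$air_temp_mean, params$air_temp_sd)
    rh <- pmin(pmax(stats::rnorm(n, params$rh_mean, params$rh_sd),
                    params$rh_range[1]), params$rh_range[2])
    irr <- pmax(stats::rnorm(n, params$irradiance_mean, params$irradiance_sd), 0)
    t_wet <- air + params$t_wet_offset + stats::rnorm(n, 0, params$ref_noise_sd)
    t_dry <- air + params$t_dry_offset + stats::rnorm(n, 0, params$ref_noise_sd)
    bad <- t_dry <= t_wet
    t_dry[bad] <- t_wet[bad] + 1  # safeguard; never triggers at defaults
    data.frame(date = seq_len(n), air_temp = air, rh = rh,
               vpd = vpd_from_weather(air, rh), irradiance = irr,
               t_wet = t_wet, t_dry = t_dry)
  })

  grid <- expand.grid(
    vine = seq_len(design$vines_per_replication),
    block = seq_len(design$n_blocks),
    treatment = design$treatments,
    date = seq_len(design$n_dates),
    side = design$sides,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  mu_grid <- cwsi_mean_grid(design, params)
  t_idx <- match(grid$treatment, design$treatments)
  mu <- mu_grid[cbind(grid$date, t_idx)]

  truth <- with_substream(seed, "truth", expr = {
    phi <- params$cwsi_precision
    cwsi <- stats::rbeta(nrow(grid), mu * phi, (1 - mu) * phi)
    side_eff <- ifelse(grid$side == design$sides[1],
                       params$side_effect_mpa, -params$side_effect_mpa)
    if (length(design$sides) == 1) side_eff <- 0
    psi <- params$psi_intercept + params$psi_slope * cwsi + side_eff +
      stats::rnorm(nrow(grid), 0, params$psi_noise_sd)
    psi <- pmin(pmax(psi, params$psi_range[1]), params$psi_range[2])
    cbind(grid[c("date", "treatment", "block", "side", "vine")],
          data.frame(psi_stem = psi, true_cwsi = cwsi))
  })

  list(weather = weather, truth = truth)
}

#' Scene parameters for rendered thermal frames
#'
#' A rendered frame has the vertical structure of a sideways canopy view: a
#' sky band on top (well below the wet reference temperature), the canopy band
#' in the middle, and a soil/fruiting-zone band at the bottom (above the dry
#' reference). The canopy band's mean temperature encodes the vine's latent
#' index: `T_canopy = t_wet + cwsi * (t_dry - t_wet)`.
#'
#' @param sky_offset sky temperature minus `t_wet`, degrees C (negative).
#' @param soil_offset soil temperature minus `t_dry`, degrees C (positive).
#' @param band_fractions fractions of image height for sky / canopy / soil;
#'   must be positive and sum to 1.
#' @param pixel_noise_sd i.i.d. Gaussian pixel noise SD, degrees C.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(sky_offset = -10, soil_offset = 5,
                         band_fractions = c(0.25, 0.5, 0.25),
                         pixel_noise_sd = 0.8) {
  check_that(sky_offset < 0, "sky must sit below t_wet (sky_offset < 0)")
  check_that(soil_offset > 0, "soil must sit above t_dry (soil_offset > 0)")
  check_that(length(band_fractions) == 3 && all(band_fractions > 0) &&
               abs(sum(band_fractions) - 1) < 1e-9,
             "band_fractions must be 3 positive values summing to 1")
  check_that(pixel_noise_sd >= 0, "pixel_noise_sd must be >= 0")
  structure(list(sky_offset = sky_offset, soil_offset = soil_offset,
                 band_fractions = band_fractions,
                 pixel_noise_sd = pixel_noise_sd),
            class = "scene_params")
}

# Row ranges (1-based, inclusive) of the three bands for a given image height.
scene_bands <- function(height, fractions) {
  sky_end <- floor(fractions[1] * height)
  canopy_end <- floor((fractions[1] + fractions[2]) * height)
  check_that(sky_end >= 1 && canopy_end > sky_end && height > canopy_end,
             "band partition degenerate at height %d", height)
  list(sky = c(1L, as.integer(sky_end)),
       canopy = c(as.integer(sky_end) + 1L, as.integer(canopy_end)),
       soil = c(as.integer(canopy_end) + 1L, as.integer(height)))
}

#' Render the thermal frame sequence for one measured vine
#'
#' Produces synthetic frames (matrices of degrees C, `height x width`) with
#' the sky / canopy / soil vertical structure of [scene_params()]. Each frame
#' index seeds its own pixel-noise substream, so rendering a subset of
#' `indices` is bit-identical to slicing a full render — the end-to-end
#' pipeline exploits this by rendering only the frames that frame selection
#' retains.
#'
#' @param truth one-row slice of the `truth` data.frame from
#'   [sample_campaign()] (fields `date`, `treatment`, `block`, `side`, `vine`,
#'   `true_cwsi` are used for seeding and the canopy temperature).
#' @param weather matching one-row slice of the `weather` data.frame (`t_wet`,
#'   `t_dry`).
#' @param camera a [camera_model()]; sets resolution and, with `traverse`, the
#'   default number of frames.
#' @param scene a [scene_params()].
#' @param traverse a [traverse_spec()]; only used for the default `n_frames`.
#' @param n_frames total frames in the (virtual) recording; defaults to
#'   [frames_per_replication()].
#' @param indices 0-based frame indices to actually render (default: all).
#' @param seed master integer seed.
#' @return list of matrices; each carries attributes `frame_index` and
#'   `metadata`.
#' @export
render_frame_sequence <- function(truth, weather, camera = camera_model(),
                                  scene = scene_params(),
                                  traverse = traverse_spec(),
                                  n_frames = NULL, indices = NULL, seed = 1L) {
  stopifnot(inherits(camera, "camera_model"), inherits(scene, "scene_params"))
  check_that(nrow(truth) == 1 && nrow(weather) == 1,
             "truth and weather must be single rows")
  check_that(weather$t_dry > weather$t_wet, "t_dry must exceed t_wet")
  if (is.null(n_frames)) n_frames <- frames_per_replication(camera, traverse)
  if (is.null(indices)) indices <- seq_len(n_frames) - 1L
  check_that(all(indices >= 0 & indices < n_frames),
             "frame indices out of range [0, n_frames)")

  width <- camera$resolution[1]
  height <- camera$resolution[2]
  bands <- scene_bands(height, scene$band_fractions)
  t_canopy <- weather$t_wet + truth$true_cwsi * (weather$t_dry - weather$t_wet)
  base_col <- numeric(height)
  base_col[bands$sky[1]:bands$sky[2]] <- weather$t_wet + scene$sky_offset
  base_col[bands$canopy[1]:bands$canopy[2]] <- t_canopy
  base_col[bands$soil[1]:bands$soil[2]] <- weather$t_dry + scene$soil_offset

  meta <- list(date = truth$date, treatment = truth$treatment,
               block = truth$block, side = truth$side, vine = truth$vine)
  lapply(indices, function(i) {
    px <- matrix(base_col, nrow = height, ncol = width)
    if (scene$pixel_noise_sd > 0) {
      noise <- with_substream(
        seed, "pixels", truth$date, truth$treatment, truth$block, truth$side,
        truth$vine, i,
        expr = stats::rnorm(height * width, 0, scene$pixel_noise_sd))
      px <- px + matrix(noise, nrow = height, ncol = width)
    }
    attr(px, "frame_index") <- as.integer(i)
    attr(px, "metadata") <- meta
    px
  })
}

#' Write campaign tables and frames to a directory
#'
#' Writes `weather.csv` and `truth.csv`, and optionally one CSV matrix per
#' frame named
#' `frame_d<date>_<treatment>_b<block>_<side>_v<vine>_f<index>.csv`
#' (frame indices are 0-based, as everywhere in the package).
#'
#' @param campaign result of [sample_campaign()].
#' @param dir output directory (created if needed).
#' @param frames optional named list: each element a list of frames from
#'   [render_frame_sequence()].
#' @return invisibly, the directory.
#' @export
write_campaign <- function(campaign, dir, frames = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(campaign$weather, file.path(dir, "weather.csv"),
                   row.names = FALSE)
  utils::write.csv(campaign$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  if (!is.null(frames)) {
    for (fr_list in frames) {
      for (px in fr_list) {
        m <- attr(px, "metadata")
        fn <- sprintf("frame_d%d_%s_b%d_%s_v%d_f%04d.csv", m$date,
                      m$treatment, m$block, m$side, m$vine,
                      attr(px, "frame_index"))
        utils::write.table(px, file.path(dir, fn), sep = ",",
                           row.names = FALSE, col.names = FALSE)
      }
    }
  }
  invisible(dir)
}

#' Read a frame written by [write_campaign()]
#'
#' @param path CSV matrix path.
#' @return numeric matrix of temperatures (degrees C).
#' @export
read_frame_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
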