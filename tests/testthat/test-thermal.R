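test_that("ROI cropping is pure index selection", {
  frame <- matrix(rnorm(256 * 320, 25), nrow = 256, ncol = 320)
  roi <- roi_spec()  # centred 135-row band
  cropped <- crop_roi(frame, roi)
  expect_identical(dim(cropped), c(135L, 320L))
  expect_identical(cropped, frame[61:195, ])

  expect_identical(crop_roi(frame, roi_spec(1, 256)), frame)
  expect_identical(nrow(crop_roi(frame, roi_spec(60, 194))), 135L)
  expect_error(crop_roi(frame, roi_spec(200, 300)), "out of bounds")
  expect_error(crop_roi(matrix(0, 100, 10), roi_spec(height = 135)), "exceeds")
})

test_that("segmentation keeps the closed reference interval", {
  refs <- reference_temperatures(t_wet = 20, t_dry = 30)
  px <- matrix(c(19, 20, 30, 31), 2, 2)
  seg <- segment_by_references(px, refs)
  expect_identical(attr(seg, "n_retained"), 2L)
  expect_identical(sort(seg[!is.na(seg)]), c(20, 30))

  inside <- matrix(seq(21, 29, length.out = 9), 3, 3)
  expect_identical(attr(segment_by_references(inside, refs), "n_retained"), 9L)
  expect_error(reference_temperatures(30, 20), "exceed")
})

test_that("cropping and segmentation commute", {
  refs <- reference_temperatures(20, 30)
  frame <- matrix(runif(64 * 32, 10, 40), nrow = 64)
  roi <- roi_spec(height = 20)
  a <- segment_by_references(crop_roi(frame, roi), refs)
  b <- crop_roi(segment_by_references(frame, refs), roi)
  expect_equal(unname(a), unname(b), ignore_attr = TRUE)
})

test_that("frame statistics use the sample standard deviation", {
  st <- frame_statistics(matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(st$t_mean, 2.5)
  expect_equal(st$t_median, 2.5)
  expect_equal(st$t_sd, 1.2909944, tolerance = 1e-6)
  expect_identical(st$n_pixels_used, 4L)

  const <- frame_statistics(matrix(25, 3, 3))
  expect_equal(c(const$t_mean, const$t_median, const$t_sd), c(25, 25, 0))

  expect_error(frame_statistics(matrix(NA_real_, 2, 2)), "empty")
})

test_that("the thermal indices hit their boundary values and identity", {
  refs <- reference_temperatures(20, 30)
  expect_equal(cwsi(20, refs), 0)
  expect_equal(cwsi(30, refs), 1)
  expect_equal(cwsi(25, refs), 0.5)
  expect_equal(ig(30, refs), 0)
  expect_equal(ig(25, refs), 1)
  expect_error(ig(20, refs), "undefined")

  # Ig = 1/CWSI - 1 on random valid triples
  set.seed(202)
  for (i in 1:1000) {
    tw <- runif(1, 10, 30)
    td <- tw + runif(1, 0.5, 15)
    tc <- runif(1, tw + 1e-3, td)
    r <- reference_temperatures(tw, td)
    expect_equal(ig(tc, r), 1 / cwsi(tc, r) - 1, tolerance = 1e-12)
  }
})

test_that("segmentation retains exactly the canopy band of a clean scene", {
  w <- weather_row(t_wet = 24, t_dry = 32)
  cam <- tiny_camera(c(40L, 40L))
  fr <- render_frame_sequence(truth_row(cwsi = 0.4), w, camera = cam,
                              scene = scene_params(pixel_noise_sd = 0),
                              n_frames = 1, seed = 1)[[1]]
  refs <- reference_temperatures(w$t_wet, w$t_dry)
  seg <- segment_by_references(fr, refs)
  # bands are 10 / 20 / 10 rows at height 40: canopy = 20 rows x 40 cols
  expect_identical(attr(seg, "n_retained"), 20L * 40L)
})

test_that("the sample table recovers the planted index on noiseless frames", {
  cfg <- small_config(seed = 6)
  cfg$scene <- scene_params(pixel_noise_sd = 0)
  camp <- sample_campaign(cfg$design, cfg$generator, cfg$seed)
  frames <- thermovine:::render_selected_frames(camp, cfg)
  east <- camp$truth[camp$truth$side == "east", ]

  with_refs <- build_sample_table(frames, camp$weather, east,
                                  feature_set = "with_refs", roi = cfg$roi)
  expect_identical(nrow(with_refs), nrow(east))
  expect_equal(with_refs$cwsi, east$true_cwsi, tolerance = 1e-6)
  expect_true(all(c("cwsi", "ig") %in% names(with_refs)))

  # segmented means are confined to the reference interval
  for (d in unique(east$date)) {
    w <- camp$weather[camp$weather$date == d, ]
    rows <- with_refs$date == d
    expect_true(all(with_refs$t_canopy_mean[rows] >= w$t_wet &
                      with_refs$t_canopy_mean[rows] <= w$t_dry))
  }

  without <- build_sample_table(frames, camp$weather, east,
                                feature_set = "without_refs", roi = cfg$roi)
  expect_identical(setdiff(names(without),
                           c("date", "treatment", "block", "side", "vine",
                             "psi_stem")),
                   feature_columns("without_refs"))
  expect_length(feature_columns("without_refs"), 4)
  expect_length(feature_columns("with_refs"), 6)
})

test_that("full-side tables have one row per measured vine", {
  cfg <- small_config(seed = 12)
  camp <- sample_campaign(cfg$design, cfg$generator, cfg$seed)
  frames <- thermovine:::render_selected_frames(camp, cfg)
  tab <- build_sample_table(frames, camp$weather, camp$truth,
                            feature_set = "with_refs", roi = cfg$roi)
  expect_identical(nrow(tab), 2L * samples_per_side(cfg$design))
  expect_false(anyNA(tab))
})
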