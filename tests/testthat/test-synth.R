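test_that("vapour pressure deficit follows the Tetens form", {
  expect_equal(vpd_from_weather(25, 100), 0)
  # frozen from the independent Tetens oracle
  # 0.6108 * exp(17.27 * 25 / 262.3) * 0.5 = 1.58397...
  expect_equal(vpd_from_weather(25, 50), 1.5840, tolerance = 1e-4)
  expect_equal(vpd_from_weather(0, 0), 0.6108, tolerance = 1e-4)
  expect_true(all(vpd_from_weather(seq(-5, 45, by = 5), 30) >= 0))
  expect_error(vpd_from_weather(25, 101), "relative_humidity")
})

test_that("campaign counting matches the design", {
  expect_identical(samples_per_side(campaign_design()), 252L)
  camp <- sample_campaign(seed = 3)
  expect_identical(nrow(camp$truth), 504L)
  expect_identical(sum(camp$truth$side == "east"), 252L)
  expect_identical(nrow(camp$weather), 7L)

  tiny <- sample_campaign(campaign_design(n_dates = 1, n_blocks = 1,
                                          vines_per_replication = 1),
                          seed = 3)
  expect_identical(sum(tiny$truth$side == "east"), 3L)  # one per treatment
})

test_that("generated weather and truth satisfy their invariants", {
  camp <- sample_campaign(seed = 41)
  w <- camp$weather
  expect_true(all(w$t_dry > w$t_wet))
  expect_true(all(w$rh >= 0 & w$rh <= 100))
  expect_true(all(w$vpd >= 0 & w$irradiance >= 0))
  expect_equal(w$vpd, vpd_from_weather(w$air_temp, w$rh))

  tr <- camp$truth
  expect_true(all(tr$psi_stem >= -2.05 & tr$psi_stem <= -0.40))
  expect_true(all(tr$true_cwsi >= 0 & tr$true_cwsi <= 1))
})

test_that("irrigation regimes are ordered and the dry regime dries down", {
  # pool several seeds so per-cell means are stable
  pooled <- do.call(rbind, lapply(1:5, function(s) sample_campaign(seed = s)$truth))
  m <- tapply(pooled$psi_stem, list(pooled$treatment, pooled$date), mean)
  expect_true(all(m["T0", ] > m["T2", ]))  # full irrigation least stressed
  # no-irrigation regime trends more negative over the season
  expect_lt(mean(m["T2", 6:7]), mean(m["T2", 1:2]))
})

test_that("identical seeds give bit-identical campaigns", {
  a <- sample_campaign(seed = 99)
  b <- sample_campaign(seed = 99)
  expect_identical(a, b)
  c <- sample_campaign(seed = 100)
  expect_false(identical(a$truth$psi_stem, c$truth$psi_stem))
})

test_that("rendered frames encode the index in the canopy band", {
  w <- weather_row(t_wet = 25, t_dry = 33)
  cam <- tiny_camera(c(64L, 64L))
  for (cw in c(0, 1)) {
    fr <- render_frame_sequence(truth_row(cwsi = cw), w, camera = cam,
                                scene = scene_params(pixel_noise_sd = 0.8),
                                n_frames = 4, seed = 5)
    canopy <- fr[[1]][17:32, ]  # middle band of a 64-row frame
    target <- if (cw == 0) 25 else 33
    se <- 0.8 / sqrt(length(canopy))
    expect_lt(abs(mean(canopy) - target), 5 * se)
  }
})

test_that("frame count defaults to the full replication recording", {
  fr <- render_frame_sequence(truth_row(), weather_row(),
                              camera = tiny_camera(c(8L, 8L)),
                              scene = scene_params(pixel_noise_sd = 0),
                              seed = 1)
  expect_length(fr, 1080)
})

test_that("rendering a subset of frames is identical to slicing a full render", {
  cam <- tiny_camera()
  sc <- scene_params(pixel_noise_sd = 0.5)
  full <- render_frame_sequence(truth_row(), weather_row(), camera = cam,
                                scene = sc, n_frames = 10, seed = 8)
  sub <- render_frame_sequence(truth_row(), weather_row(), camera = cam,
                               scene = sc, n_frames = 10,
                               indices = c(3L, 7L), seed = 8)
  expect_identical(sub[[1]], full[[4]])
  expect_identical(sub[[2]], full[[8]])
})

test_that("campaign tables and frames round-trip through disk", {
  dir <- withr::local_tempdir()
  camp <- sample_campaign(campaign_design(n_dates = 1, n_blocks = 1), seed = 2)
  fr <- render_frame_sequence(camp$truth[1, ],
                              camp$weather[1, ], camera = tiny_camera(),
                              n_frames = 2, seed = 2)
  write_campaign(camp, dir, frames = list(fr))
  expect_true(file.exists(file.path(dir, "weather.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  back <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(back$psi_stem, camp$truth$psi_stem)
  frame_files <- list.files(dir, pattern = "^frame_")
  expect_length(frame_files, 2)
  px <- read_frame_csv(file.path(dir, frame_files[1]))
  expect_equal(unname(px), unname(fr[[1]]), ignore_attr = TRUE)
})

test_that("scene parameter validation guards the band structure", {
  expect_error(scene_params(sky_offset = 1), "sky")
  expect_error(scene_params(band_fractions = c(0.5, 0.5, 0.5)), "band_fractions")
  # degenerate partition at tiny heights is a configuration error
  expect_error(
    render_frame_sequence(truth_row(), weather_row(),
                          camera = tiny_camera(c(4L, 2L)),
                          n_frames = 1, seed = 1),
    "degenerate")
})
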