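test_that("RT map of a static target peaks at the true range for all times", {
  cfg <- tiny_config(4L)
  rt <- range_time_map(linear_cube(3.0, 0, cfg))
  ridge <- map_ridge(rt)
  expect_true(all(abs(ridge - 3.0) < range_bin_width(cfg)))
  expect_equal(rt$feature_axis,
               (seq_len(cfg$samples_per_chirp) - 1) * range_bin_width(cfg))
  expect_equal(rt$time_axis[2] - rt$time_axis[1], chirp_interval(cfg))
})

test_that("an all-zero cube collapses to a uniform floor map", {
  cfg <- tiny_config(2L)
  tr <- constant_rate_trajectory(3, 0, duration = record_duration(cfg) + 0.01)
  cube <- synthesize_cube(tr, cfg, NULL, target_amplitude = 0)
  rt <- range_time_map(cube)
  expect_equal(length(unique(as.vector(rt$values))), 1L)
})

test_that("RT map conserves cube power when the floor is disabled", {
  cfg <- tiny_config(3L)
  cube <- linear_cube(4.2, -0.4, cfg, noise_spec(snr_db = 8), seed = 3)
  rt <- range_time_map(cube, floor_db = Inf)
  expect_equal(sum(10^(rt$values / 10)), sum(Mod(cube$samples)^2),
               tolerance = 1e-6)
})

test_that("a walking-then-backward-fall ridge decreases then increases", {
  cfg <- desk_radar_config()
  tr <- trajectory_template("backward_fall", "toward_radar", seed = 4,
                            duration = record_duration(cfg) + 0.01)
  cube <- synthesize_cube(tr, cfg, NULL)
  rt <- range_time_map(cube, decimate = 16L)
  ridge <- map_ridge(rt)
  k <- which.min(ridge)
  expect_gt(k, 1)
  expect_lt(k, length(ridge))
  expect_gt(ridge[1] - ridge[k], 2 * range_bin_width(cfg))
  expect_gt(ridge[length(ridge)] - ridge[k], 2 * range_bin_width(cfg))
})

test_that("DT ridge sign equals the sign of the range rate", {
  cfg <- desk_radar_config(n_frames = 8L)
  for (rate in c(-0.8, -0.25, 0.4, 1.0)) {
    cube <- linear_cube(4, rate, cfg)
    dt <- doppler_time_map(cube)
    ridge <- map_ridge(dt)
    expect_true(all(sign(ridge) == sign(rate)),
                info = sprintf("rate %.2f", rate))
    # magnitude matches 2 fc (dd/dt) / c within one Doppler bin
    fd <- 2 * cfg$start_frequency * rate / 299792458
    bin <- (1 / chirp_interval(cfg)) / 64
    expect_lt(max(abs(ridge - fd)), bin)
  }
})

test_that("a static target pins the DT ridge at zero Doppler", {
  cfg <- desk_radar_config(n_frames = 6L)
  dt <- doppler_time_map(linear_cube(3, 0, cfg))
  expect_true(all(map_ridge(dt) == 0))
})

test_that("conjugating the cube mirrors the Doppler axis", {
  cfg <- desk_radar_config(n_frames = 6L)
  cube <- linear_cube(4, -0.6, cfg, noise_spec(snr_db = 10), seed = 8)
  dt <- doppler_time_map(cube, floor_db = Inf)
  cube$samples <- Conj(cube$samples)
  dtc <- doppler_time_map(cube, floor_db = Inf)
  # bin k (frequency f) maps to bin n - k (frequency -f); drop the
  # unpaired most-negative bin
  n <- nrow(dt$values)
  expect_equal(dtc$values[2:n, ], dt$values[n:2, ], tolerance = 1e-6)
})

test_that("STFT parameter validation guards the window geometry", {
  expect_error(stft_params(window_length = 16, hop = 32), "hop")
  expect_error(stft_params(window_length = 64, fft_length = 32), "fft_length")
  cfg <- tiny_config(2L)
  cube <- linear_cube(3, 0, cfg)
  expect_error(doppler_time_map(cube, stft_params(window_length = 512L,
                                                  fft_length = 512L)),
               "longer than the record")
})

test_that("speckle injection records its mask and respects the rate cap", {
  cfg <- tiny_config(4L)
  rt <- range_time_map(linear_cube(3, 0, cfg, noise_spec(), seed = 2))
  out <- inject_outliers(rt, rate = 0.01, gain_db = 20, seed = 5)
  mask <- out$provenance$outlier_mask
  expect_equal(dim(mask), dim(rt$values))
  expect_true(all(out$values[mask] == mean(rt$values) + 20))
  expect_identical(out$values[!mask], rt$values[!mask])
  expect_error(inject_outliers(rt, rate = 0.5), "0.05")
  # deterministic in the seed
  out2 <- inject_outliers(rt, rate = 0.01, gain_db = 20, seed = 5)
  expect_identical(out$values, out2$values)
})

test_that("cropping preserves axis/metadata consistency", {
  cfg <- tiny_config(3L)
  rt <- range_time_map(linear_cube(3, 0, cfg))
  cr <- crop_map(rt, 1, 6)
  expect_true(all(cr$feature_axis >= 1 & cr$feature_axis <= 6))
  expect_equal(nrow(cr$values), length(cr$feature_axis))
  expect_error(crop_map(rt, 100, 200), "empty")
})

test_that("maps render to PNG files", {
  cfg <- tiny_config(2L)
  rt <- range_time_map(linear_cube(3, 0, cfg, noise_spec(), seed = 1))
  path <- tempfile(fileext = ".png")
  render_png(rt, path)
  expect_true(file.exists(path))
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], dim(rt$values))
})
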