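test_that("static target concentrates every chirp at the true range bin", {
  cfg <- tiny_config(4L)
  cube <- linear_cube(3.0, 0, cfg)
  f <- Mod(stats::mvfft(cube$samples))^2
  peaks <- apply(f, 2, which.max)
  expect_equal(length(unique(peaks)), 1L)
  d_hat <- (peaks[1] - 1) * range_bin_width(cfg)
  expect_lt(abs(d_hat - 3.0), range_bin_width(cfg))
})

test_that("noise-only cubes carry the configured noise power", {
  cfg <- tiny_config(4L)
  ns <- noise_spec(snr_db = 10, clutter_amplitude = 0)
  tr <- constant_rate_trajectory(3, 0, duration = record_duration(cfg) + 0.01)
  cube <- synthesize_cube(tr, cfg, ns, seed = 5, target_amplitude = 0)
  p <- mean(Mod(cube$samples)^2)
  expected <- 10^(-10 / 10)
  expect_lt(abs(10 * log10(p / expected)), 3)
})

test_that("synthesis is bit-identical under a fixed seed", {
  cfg <- tiny_config(3L)
  ns <- noise_spec(snr_db = 5)
  tr <- trajectory_template("left_fall", "toward_radar", seed = 2,
                            duration = record_duration(cfg) + 0.01)
  a <- synthesize_cube(tr, cfg, ns, seed = 99)
  b <- synthesize_cube(tr, cfg, ns, seed = 99)
  expect_identical(a$samples, b$samples)
  c <- synthesize_cube(tr, cfg, ns, seed = 100)
  expect_false(identical(a$samples, c$samples))
})

test_that("cube dimensions follow the config and short trajectories fail", {
  cfg <- tiny_config(5L)
  cube <- linear_cube(4, -0.3, cfg)
  expect_equal(dim(cube$samples),
               c(cfg$samples_per_chirp, n_chirps(cfg)))
  short <- constant_rate_trajectory(4, 0, duration = 0.1)
  expect_error(synthesize_cube(short, cfg), "record spans")
})

test_that("generated datasets are balanced with reproducible manifests", {
  cfg <- tiny_config(3L)
  ds <- generate_dataset(4, cfg, noise_spec(), seed = 11)
  expect_length(ds$cubes, 20L)
  expect_equal(nrow(ds$manifest), 20L)
  expect_true(all(table(ds$manifest$label) == 4L))
  # motion classes alternate approach sides; nonmotion is static
  motion <- subset(ds$manifest, label != "nonmotion_fall")
  expect_true(all(c("toward_radar", "away_from_radar") %in% motion$approach))
  expect_true(all(subset(ds$manifest,
                         label == "nonmotion_fall")$approach == "static"))
  ds2 <- generate_dataset(4, cfg, noise_spec(), seed = 11)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$cubes[[7]]$samples, ds2$cubes[[7]]$samples)
  # heights stay in the requested band
  expect_true(all(ds$manifest$height_m >= 1.5 & ds$manifest$height_m <= 1.9))
})
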