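test_that("config validation enforces the waveform invariants", {
  expect_s3_class(radar_config(), "radar_config")
  # slope inconsistent with bandwidth/duration by > 1% warns
  expect_warning(radar_config(chirp_slope = 60e12), "deviates")
  # ADC window longer than the ramp is impossible
  expect_error(radar_config(samples_per_chirp = 512L), "exceeds chirp")
  expect_error(radar_config(chirps_per_frame = 0L), "count")
  expect_error(radar_config(bandwidth = -1), "positive")
  expect_error(noise_spec(outlier_rate = 0.2), "0.05")
  expect_error(noise_spec(snr_db = Inf), "finite")
})

test_that("beat frequency follows the chirp-delay relation", {
  cfg <- radar_config()
  # fb = 2 d beta / c at d = 3 m, Table-2 slope: just above 1 MHz
  fb <- beat_frequency(3, cfg)
  expect_equal(fb, 2 * 3 * cfg$chirp_slope / 299792458)
  expect_equal(fb / 1e6, 1.006, tolerance = 1e-3)
  # linearity and the d -> 0+ limit
  expect_equal(beat_frequency(6, cfg), 2 * fb)
  expect_lt(beat_frequency(1e-9, cfg), 1)
  expect_error(beat_frequency(-1, cfg), "positive")
  expect_error(beat_frequency(0, cfg), "positive")
})

test_that("range_from_beat inverts beat_frequency to machine precision", {
  cfg <- radar_config()
  set.seed(11)
  d <- runif(100, 0.1, 12)
  expect_equal(range_from_beat(beat_frequency(d, cfg), cfg), d,
               tolerance = 1e-12)
  expect_identical(range_from_beat(0, cfg), 0)
  expect_error(range_from_beat(-5, cfg), "non-negative")
})

test_that("derived quantities are consistent with the sampled bandwidth", {
  cfg <- radar_config()
  b_sampled <- cfg$chirp_slope * cfg$samples_per_chirp / cfg$sample_rate
  expect_equal(range_bin_width(cfg), 299792458 / (2 * b_sampled))
  expect_equal(chirp_interval(cfg), 160e-6)
  expect_equal(n_chirps(tiny_config(2L)), 256L)
  # desk profile: 400 us chirp interval, ~3 s record
  dc <- desk_radar_config()
  expect_equal(chirp_interval(dc), 400e-6)
  expect_equal(record_duration(dc), 59 * 128 * 400e-6)
})
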