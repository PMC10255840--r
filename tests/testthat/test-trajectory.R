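grid_eval <- function(tr, n = 600) {
  t <- seq(0, tr$duration, length.out = n)
  list(t = t, d = tr$d_of_t(t))
}

test_that("backward fall toward the radar reverses its range trend", {
  tr <- trajectory_template("backward_fall", "toward_radar",
                            subject_height = 1.75, walk_speed = 1, seed = 7)
  g <- grid_eval(tr)
  pre <- g$d[g$t < tr$fall_onset]
  fall <- g$d[g$t > tr$fall_onset & g$t < tr$fall_onset + tr$fall_duration]
  expect_true(all(diff(pre) < 0))   # strictly approaching while walking
  expect_true(all(diff(fall) > 0))  # strictly receding during the fall
})

test_that("forward/left falls keep a monotone range trend", {
  for (lb in c("forward_fall", "left_fall")) {
    tr <- trajectory_template(lb, "toward_radar", seed = 3)
    g <- grid_eval(tr)
    expect_true(all(diff(g$d) <= 1e-12), info = lb)
    # mirrored when walking away
    tr2 <- trajectory_template(lb, "away_from_radar", seed = 3)
    g2 <- grid_eval(tr2)
    expect_true(all(diff(g2$d) >= -1e-12), info = lb)
  }
})

test_that("nonmotion fall is static before onset and excursive after", {
  tr <- trajectory_template("nonmotion_fall", "static", walk_speed = 0,
                            seed = 1)
  g <- grid_eval(tr)
  pre <- g$d[g$t < tr$fall_onset]
  expect_equal(diff(range(pre)), 0)
  expect_equal(abs(tr$d_of_t(tr$duration) - tr$d_of_t(0)), tr$excursion,
               tolerance = 1e-9)
})

test_that("fall excursion grows with subject height", {
  exc <- function(h, seed) {
    tr <- trajectory_template("forward_fall", "toward_radar",
                              subject_height = h, seed = seed)
    tr$excursion
  }
  for (seed in c(1, 5, 9))
    expect_gt(exc(1.85, seed), exc(1.58, seed))
})

test_that("forward excursions dominate left, backward dominate right", {
  for (seed in 1:5) {
    e <- vapply(c("forward_fall", "left_fall", "backward_fall",
                  "right_fall"), function(lb)
      trajectory_template(lb, "toward_radar", seed = seed)$excursion,
      numeric(1))
    expect_gt(e[["forward_fall"]], e[["left_fall"]])
    expect_gt(e[["backward_fall"]], e[["right_fall"]])
  }
})

test_that("trajectories stay positive and chirp-continuous", {
  cfg <- desk_radar_config()
  ti <- chirp_interval(cfg)
  for (seed in 1:10) {
    lb <- sample(fall_labels(), 1)
    ap <- if (lb == "nonmotion_fall") "static"
          else sample(c("toward_radar", "away_from_radar"), 1)
    tr <- trajectory_template(lb, ap, seed = seed,
                              duration = record_duration(cfg) + 0.01)
    d <- tr$d_of_t((0:(n_chirps(cfg) - 1)) * ti)
    expect_true(all(d > 0))
    expect_lt(max(abs(diff(d))), 10 * max(tr$walk_speed, 1) * ti)
  }
})

test_that("invalid labels and approaches are rejected by name", {
  expect_error(trajectory_template("sideways", "toward_radar"),
               "unknown label")
  expect_error(trajectory_template("forward_fall", "static"),
               "only valid")
  expect_error(fall_trajectory(identity, "forward_fall", "sideways", 1),
               "unknown approach")
  expect_error(trajectory_template("forward_fall", "toward_radar",
                                   subject_height = 1.2), "1.4")
})

test_that("templates are deterministic in the seed", {
  a <- trajectory_template("right_fall", "away_from_radar", seed = 42)
  b <- trajectory_template("right_fall", "away_from_radar", seed = 42)
  t <- seq(0, a$duration, length.out = 100)
  expect_identical(a$d_of_t(t), b$d_of_t(t))
  c <- trajectory_template("right_fall", "away_from_radar", seed = 43)
  expect_false(identical(a$d_of_t(t), c$d_of_t(t)))
})
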