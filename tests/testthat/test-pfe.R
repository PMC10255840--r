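test_that("adaptive threshold reproduces its closed forms", {
  m <- matrix(c(0, 5, 10), 1)
  expect_equal(adaptive_threshold(m, 0)$threshold, 5)      # mean
  expect_equal(adaptive_threshold(m, 0.5)$threshold, 7.5)  # 0.5*5 + 0.5*10
  expect_equal(adaptive_threshold(m, 1)$threshold, 10)     # max + min
  # at a = 0.5 only the 10-cell survives
  out <- adaptive_threshold(m, 0.5)$map
  expect_equal(as.vector(out), c(0, 0, 10))
  expect_error(adaptive_threshold(m, 1.5), "\\[0, 1\\]")
  expect_error(adaptive_threshold(matrix(c(1, NA), 1), 0.5), "finite")
})

test_that("threshold stays within its bounds on random maps", {
  set.seed(31)
  for (i in 1:50) {
    m <- matrix(runif(120, 0, 10), 10)
    a <- runif(1)
    pth <- adaptive_threshold(m, a)$threshold
    expect_gte(pth, min(m))
    expect_lte(pth, max(m) + min(m))
  }
})

test_that("the surviving-cell set shrinks as the threshold weight grows", {
  set.seed(17)
  m <- matrix(runif(400, 0, 30), 20)  # min(P) >= 0
  survivors <- function(a) {
    pth <- adaptive_threshold(m, a)$threshold
    which(m >= pth)
  }
  prev <- survivors(0)
  for (a in seq(0.1, 1, by = 0.1)) {
    cur <- survivors(a)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("hampel filter matches the brute-force oracle on random series", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    # sprinkle spikes and ties
    x[sample(n, max(1, n %/% 10))] <- rnorm(1) * 50
    if (i %% 3 == 0) x <- round(x, 1)
    K <- sample(1:5, 1)
    nth <- runif(1, 0.5, 4)
    expect_equal(as.numeric(hampel_filter(x, K, nth)),
                 hampel_reference(x, K, nth))
  }
})

test_that("hampel handles the canonical spike, constants, and ramps", {
  x <- c(1, 1, 1, 100, 1, 1, 1)
  expect_equal(as.numeric(hampel_filter(x, 2, 3)), rep(1, 7))
  expect_equal(attr(hampel_filter(x, 2, 3), "n_replaced"), 1L)
  # constant series untouched for any parameters
  expect_equal(as.numeric(hampel_filter(rep(4.2, 20), 3, 1)), rep(4.2, 20))
  # strictly monotone ramp untouched
  expect_equal(as.numeric(hampel_filter(1:10, 1, 3)), as.numeric(1:10))
  # length-1 series is its own window
  expect_equal(as.numeric(hampel_filter(5, 2, 3)), 5)
})

test_that("hampel output never leaves the window's original range", {
  set.seed(202)
  for (i in 1:50) {
    x <- rnorm(40) * sample(c(1, 100), 40, replace = TRUE)
    K <- sample(1:4, 1)
    y <- as.numeric(hampel_filter(x, K, 3))
    for (k in seq_along(x)) {
      w <- x[max(1, k - K):min(length(x), k + K)]
      expect_gte(y[k], min(w))
      expect_lte(y[k], max(w))
    }
  }
})

test_that("pfe_clean removes injected speckle and records provenance", {
  cfg <- desk_radar_config(n_frames = 12L)
  cube <- linear_cube(3.5, -0.5, cfg, noise_spec(snr_db = 15), seed = 9)
  rt <- range_time_map(cube, decimate = 8L)
  rt <- inject_outliers(rt, rate = 0.01, gain_db = 15, seed = 3)
  cleaned <- pfe_clean(rt, pfe_params())
  prov <- cleaned$provenance$pfe
  expect_named(prov, c("a", "hampel_k", "hampel_nth", "threshold",
                       "n_replaced"))
  expect_gt(prov$n_replaced, 0)
  # injected cells should no longer exceed their local median + nth * S
  mask <- rt$provenance$outlier_mask
  K <- 5L; nth <- 3
  bad <- 0L
  for (idx in which(mask)) {
    i <- (idx - 1) %% nrow(mask) + 1
    j <- (idx - 1) %/% nrow(mask) + 1
    w <- cleaned$values[i, max(1, j - K):min(ncol(mask), j + K)]
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    if (cleaned$values[i, j] > m + nth * s) bad <- bad + 1L
  }
  expect_gte(1 - bad / sum(mask), 0.9)
})

test_that("pfe_clean is nearly idempotent on simulated maps", {
  cfg <- tiny_config(6L)
  cube <- linear_cube(4, -0.4, cfg, noise_spec(snr_db = 12), seed = 13)
  rt <- inject_outliers(range_time_map(cube, decimate = 4L), 0.01, 15,
                        seed = 2)
  once <- pfe_clean(rt, pfe_params())
  twice <- pfe_clean(once, pfe_params())
  changed <- mean(twice$values != once$values)
  expect_lt(changed, 0.01)
})

test_that("a clean smooth ridge passes through pfe_clean untouched", {
  # floor map with one smooth constant-level ridge
  v <- matrix(0, 20, 80)
  v[9, ] <- 10
  fm <- structure(list(values = v, kind = "RT",
                       feature_axis = seq_len(20), time_axis = seq_len(80),
                       provenance = list()), class = "feature_map")
  out <- pfe_clean(fm, pfe_params(a = 0.25))
  expect_equal(out$values, v)
})

test_that("pfe parameter validation", {
  expect_error(pfe_params(a = -0.1), "\\[0, 1\\]")
  expect_error(pfe_params(hampel_k = 0), "count")
  expect_error(pfe_params(hampel_nth = -1), "> 0")
})
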