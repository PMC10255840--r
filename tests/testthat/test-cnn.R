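# small random image-pair set used across the training tests
toy_set <- function(n, size = 54L, seed = 1) {
  set.seed(seed)
  list(x_rt = array(runif(size * size * 3 * n), c(size, size, 3, n)),
       x_dt = array(runif(size * size * 3 * n), c(size, size, 3, n)),
       labels = factor(rep(fall_labels(), length.out = n),
                       levels = fall_labels()))
}

test_that("the dimension chain matches the architecture table", {
  d <- network_dims(54)
  expect_equal(d$conv_size, c(52L, 24L, 10L, 3L))
  expect_equal(d$pooled_size, c(26L, 12L, 5L, 3L))
  expect_equal(d$flatten, 1152L)
  expect_equal(d$merged, 2304L)
  # inconsistent input sizes name the offending layer
  expect_error(network_dims(9), "layer")
  expect_error(network_dims(53), "max-pool layer 1")
})

test_that("weight shapes follow the spec and zero weights give 0.2 each", {
  w <- radarfall:::.cnn_init(1L, 54L)
  expect_equal(dim(w$rt_W1), c(27, 16))
  expect_equal(dim(w$dt_W4), c(576, 128))
  expect_equal(dim(w$fc_W), c(2304, 5))
  zero <- lapply(w, function(m) m * 0)
  ts <- toy_set(4)
  fit <- structure(list(weights = zero, classes = fall_labels(),
                        input_size = 54L), class = "fall_cnn")
  p <- predict(fit, ts$x_rt, ts$x_dt, type = "prob")
  expect_equal(as.vector(p), rep(0.2, 20), tolerance = 1e-7)
})

test_that("probabilities are a proper distribution over the 5 classes", {
  ts <- toy_set(6, seed = 3)
  fit <- fall_cnn(ts$x_rt, ts$x_dt, ts$labels,
                  train_config(epochs = 1, seed = 2), validation = "none")
  p <- predict(fit, ts$x_rt, ts$x_dt, type = "prob")
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("a zero learning rate leaves the weights untouched", {
  ts <- toy_set(8)
  w0 <- radarfall:::.cnn_init(7L, 54L)
  fit <- fall_cnn(ts$x_rt, ts$x_dt, ts$labels,
                  train_config(learning_rate = 0, epochs = 3, seed = 7),
                  validation = "none", weights = w0)
  for (nm in names(w0))
    expect_equal(fit$weights[[nm]], w0[[nm]], tolerance = 1e-7)
})

test_that("the network memorises a 20-sample toy set", {
  ts <- toy_set(20, seed = 9)
  fit <- fall_cnn(ts$x_rt, ts$x_dt, ts$labels,
                  train_config(epochs = 50, seed = 1), validation = "none")
  expect_equal(fit$history$train_accuracy[50], 1.0)
  # late-training accuracy is more stable than early training
  expect_lt(var(fit$history$train_accuracy[41:50]),
            var(fit$history$train_accuracy[1:10]) + 1e-12)
})

test_that("training is reproducible from the seed", {
  ts <- toy_set(15, seed = 4)
  tc <- train_config(epochs = 4, seed = 21)
  a <- fall_cnn(ts$x_rt, ts$x_dt, ts$labels, tc, validation = "none")
  b <- fall_cnn(ts$x_rt, ts$x_dt, ts$labels, tc, validation = "none")
  expect_identical(a$history, b$history)
  expect_identical(a$weights, b$weights)
})

test_that("the internal split is stratified, disjoint and recorded", {
  ts <- toy_set(50, seed = 8)
  fit <- fall_cnn(ts$x_rt, ts$x_dt, ts$labels,
                  train_config(epochs = 1, seed = 5))
  expect_length(intersect(fit$split$train, fit$split$test), 0)
  expect_equal(sort(c(fit$split$train, fit$split$test)), 1:50)
  expect_true(all(table(ts$labels[fit$split$train]) == 8))
  expect_true(all(is.finite(fit$history$val_accuracy)))
})

test_that("degenerate training inputs are rejected", {
  ts <- toy_set(6)
  one_class <- factor(rep("forward_fall", 6), levels = fall_labels())
  expect_error(fall_cnn(ts$x_rt, ts$x_dt, one_class,
                        train_config(epochs = 1)), "2 classes")
  expect_error(fall_cnn(ts$x_rt, ts$x_dt, rep("oops", 6),
                        train_config(epochs = 1)), "outside")
  expect_error(fall_cnn(ts$x_rt[, , , 1:3], ts$x_dt, ts$labels,
                        train_config(epochs = 1)), "matching")
})
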