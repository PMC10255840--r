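#' Convert a feature map to a network input tensor
#'
#' Min-max normalises the map to `[0, 1]`, resamples it to
#' `size x size` by bilinear interpolation, and replicates the result to
#' three identical channels (the network consumes three-channel images;
#' grayscale replication avoids an arbitrary colormap choice).  A
#' degenerate constant map becomes an all-0.5 image with a warning.
#' Because of the min-max normalisation, maps differing by a constant dB
#' offset produce identical tensors.
#'
#' @param map a `feature_map` or numeric matrix.
#' @param size output height/width (default 54, the network input).
#' @return numeric array of dimension `c(size, size, 3)` with values in
#'   `[0, 1]`.
#' @export
preprocess_map <- function(map, size = 54L) {
  v <- if (inherits(map, "feature_map")) map$values else map
  stopifnot(is.numeric(v), is.matrix(v))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warnf("preprocess_map: constant map; emitting a flat 0.5 image")
    v <- matrix(0.5, nrow(v), ncol(v))
  } else {
    v <- (v - rng[1]) / (rng[2] - rng[1])
  }
  r <- .resize_bilinear(v, as.integer(size), as.integer(size))
  array(rep(r, 3L), dim = c(size, size, 3L))
}

# stack a list of (size, size, 3) tensors into a (size, size, 3, N) array
stack_images <- function(lst) {
  stopifnot(length(lst) >= 1L)
  d <- dim(lst[[1]])
  array(unlist(lst, use.names = FALSE), dim = c(d, length(lst)))
}

#' Layer-by-layer dimension chain of the dual-branch network
#'
#' Each branch is Conv(3->16, 3x3) -> MaxPool(2) -> Conv(16->32, 3x3) ->
#' MaxPool(2) -> Conv(32->64, 3x3) -> MaxPool(2) -> Conv(64->128, 3x3) ->
#' Flatten, with valid (no-padding) convolutions; the two flattened
#' branches are concatenated and a fully connected layer produces the
#' five class scores, normalised by softmax.  For the default 54x54
#' input the flatten is 1x1152 per branch and 1x2304 after merging.
#' Inconsistent input sizes (a pool meeting an odd width) raise an error
#' naming the offending layer.
#'
#' @param input_size input image height/width.
#' @return list with `conv_size`, `pooled_size` (per conv layer),
#'   `flatten` and `merged` widths.
#' @examples
#' network_dims(54)$flatten   # 1152
#' @export
network_dims <- function(input_size = 54L) {
  .cnn_dims(as.integer(input_size))
}

#' Training hyperparameters for the dual-branch network
#'
#' Defaults follow the training protocol used throughout the package:
#' Adam at learning rate 5e-4, 50 epochs, step learning-rate decay
#' (halved every 10 epochs), batch size 32, stratified 80/20 split.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param step_size epochs between learning-rate decays.
#' @param gamma multiplicative decay factor.
#' @param batch_size minibatch size.
#' @param split_fraction fraction of samples used for training when
#'   [fall_cnn()] performs the split itself.
#' @param seed seed for initialisation, shuffling and the split.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, epochs = 50L,
                         step_size = 10L, gamma = 0.5, batch_size = 32L,
                         split_fraction = 0.8, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate < 0)
    stopf("train_config: learning_rate must be >= 0")
  if (!is_count(epochs)) stopf("train_config: epochs must be a count >= 1")
  if (!is_count(step_size) || !is_count(batch_size))
    stopf("train_config: step_size and batch_size must be counts")
  if (!is.numeric(split_fraction) || split_fraction <= 0 ||
      split_fraction >= 1)
    stopf("train_config: split_fraction must lie in (0, 1)")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 step_size = as.integer(step_size), gamma = gamma,
                 batch_size = as.integer(batch_size),
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/test split
#'
#' @param labels factor or character vector of class labels.
#' @param fraction fraction assigned to the training set, per class.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, fraction = 0.8, seed = 1L) {
  labels <- as.character(labels)
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(length(idx) * fraction)
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Fit the dual-branch fall-direction classifier
#'
#' Trains the two-branch convolutional network on paired range-time and
#' Doppler-time image tensors.  Each branch extracts features from one
#' map kind; the flattened branch outputs (1x1152 each for 54x54 inputs)
#' are concatenated (1x2304) and a fully connected softmax layer yields
#' the five class probabilities.  Training minimises cross-entropy with
#' Adam under a step learning-rate decay; every random draw
#' (initialisation, shuffling, the internal split) derives from
#' `config$seed`, so refits with identical inputs reproduce the history
#' exactly.
#'
#' @param x_rt,x_dt numeric arrays `c(S, S, 3, N)` of preprocessed
#'   range-time and Doppler-time images (see [preprocess_map()]).
#' @param labels factor or character vector of length N with levels drawn
#'   from [fall_labels()].
#' @param config a [train_config()].
#' @param validation `NULL` to carve a stratified
#'   `1 - config$split_fraction` validation share out of the data
#'   (indices recorded in the fit), `"none"` to train on everything, or
#'   a list `list(x_rt =, x_dt =, labels =)` with held-out data.
#' @param weights optional initial weight list (as returned by
#'   `coef.fall_cnn`); defaults to seeded He initialisation.
#' @return an object of class `fall_cnn`: weights, per-epoch `history`
#'   (train/validation loss and accuracy), the class levels, the split
#'   bookkeeping, and the configuration.
#' @seealso [predict.fall_cnn()], [evaluate_classifier()]
#' @export
fall_cnn <- function(x_rt, x_dt, labels, config = train_config(),
                     validation = NULL, weights = NULL) {
  stopifnot(inherits(config, "train_config"))
  dims <- dim(x_rt)
  if (length(dims) != 4L || !all(dims == dim(x_dt)) || dims[3] != 3L)
    stopf("x_rt and x_dt must be matching (S, S, 3, N) arrays")
  s <- dims[1]
  n <- dims[4]
  classes <- fall_labels()
  y <- factor(as.character(labels), levels = classes)
  if (any(is.na(y))) stopf("labels contain values outside fall_labels()")
  if (length(y) != n) stopf("length(labels) != number of images")
  if (length(unique(y)) < 2L)
    stopf("training data must contain at least 2 classes")

  split <- NULL
  if (is.null(validation)) {
    split <- stratified_split(y, config$split_fraction, config$seed)
    val <- list(x_rt = x_rt[, , , split$test, drop = FALSE],
                x_dt = x_dt[, , , split$test, drop = FALSE],
                labels = y[split$test])
    x_rt <- x_rt[, , , split$train, drop = FALSE]
    x_dt <- x_dt[, , , split$train, drop = FALSE]
    y_tr <- y[split$train]
  } else if (identical(validation, "none")) {
    val <- NULL
    y_tr <- y
  } else {
    val <- validation
    val$labels <- factor(as.character(val$labels), levels = classes)
    y_tr <- y
  }
  if (length(y_tr) == 0L) stopf("empty training split")

  if (is.null(weights)) weights <- .cnn_init(config$seed, as.integer(s))
  empty <- array(0, dim = c(s, s, 3, 0))
  fit <- .cnn_train(
    weights, x_rt, x_dt, as.integer(y_tr) - 1L,
    if (is.null(val)) empty else val$x_rt,
    if (is.null(val)) empty else val$x_dt,
    if (is.null(val)) integer(0) else as.integer(val$labels) - 1L,
    list(learning_rate = config$learning_rate, epochs = config$epochs,
         batch_size = config$batch_size, step_size = config$step_size,
         gamma = config$gamma, seed = config$seed,
         input_size = as.integer(s)))

  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = fit$train_loss,
                        train_accuracy = fit$train_accuracy,
                        val_loss = fit$val_loss,
                        val_accuracy = fit$val_accuracy)
  structure(list(weights = fit$weights, history = history,
                 classes = classes, input_size = s, config = config,
                 split = split, n_train = length(y_tr),
                 call = match.call()), class = "fall_cnn")
}

#' Predict fall directions from paired map images
#'
#' @param object a fitted [fall_cnn()].
#' @param x_rt,x_dt arrays `c(S, S, 3, N)` of preprocessed images.
#' @param type `"class"` for hard labels, `"prob"` for the N x 5
#'   probability matrix (rows sum to 1).
#' @param ... unused.
#' @return factor of predicted labels, or a probability matrix.
#' @export
predict.fall_cnn <- function(object, x_rt, x_dt,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (length(dim(x_rt)) == 3L) dim(x_rt) <- c(dim(x_rt), 1L)
  if (length(dim(x_dt)) == 3L) dim(x_dt) <- c(dim(x_dt), 1L)
  p <- .cnn_forward(object$weights, x_rt, x_dt,
                    as.integer(object$input_size))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

#' @export
coef.fall_cnn <- function(object, ...) object$weights

#' @export
print.fall_cnn <- function(x, ...) {
  d <- network_dims(x$input_size)
  cat("Dual-branch CNN fall-direction classifier\n")
  cat(sprintf("  input 2 x (%d x %d x 3); flatten %d/branch, merged %d; 5 classes\n",
              x$input_size, x$input_size, d$flatten, d$merged))
  cat(sprintf("  trained %d epochs on %d samples (lr %.2g, batch %d)\n",
              x$config$epochs, x$n_train, x$config$learning_rate,
              x$config$batch_size))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final train accuracy %.3f%s\n", h$train_accuracy,
              if (is.finite(h$val_accuracy))
                sprintf(", validation accuracy %.3f", h$val_accuracy)
              else ""))
  invisible(x)
}

#' @export
summary.fall_cnn <- function(object, ...) {
  print(object)
  npar <- sum(vapply(object$weights, length, numeric(1)))
  cat(sprintf("  parameters: %d\n", as.integer(npar)))
  cat("\nTraining history (last 5 epochs):\n")
  print(tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @param x a fitted `fall_cnn`.
#' @param ... unused.
#' @rdname fall_cnn
#' @export
plot.fall_cnn <- function(x, ...) {
  h <- x$history
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  has_val <- any(is.finite(h$val_accuracy))
  plot(h$epoch, h$train_accuracy, type = "l", ylim = c(0, 1),
       xlab = "epoch", ylab = "accuracy", main = "accuracy")
  if (has_val) lines(h$epoch, h$val_accuracy, lty = 2)
  if (has_val) legend("bottomright", c("train", "validation"),
                      lty = c(1, 2), bty = "n")
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "loss")
  if (has_val) lines(h$epoch, h$val_loss, lty = 2)
  invisible(x)
}
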