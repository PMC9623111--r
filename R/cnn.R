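# One-dimensional CNN regression head for spectra.
#
# Architecture: five valid-padding conv layers (16 filters, kernel length 3,
# stride 1, ReLU) -> max pool (size 2, stride 2) -> global average pool ->
# dense layer to a single output. Trained with mini-batch RMSProp on a mean
# absolute error loss. All randomness (weight initialization) comes from R's
# seeded RNG; the optimization itself is deterministic, so a (data, config,
# seed) triple fully reproduces a model.

#' CNN configuration
#'
#' Defaults: 5 conv layers of 16 length-3 kernels at stride 1, max pooling
#' (size 2, stride 2), global average pooling, a single dense output;
#' RMSProp with learning rate 0.001, gradient decay 0.9, no learning-rate
#' decay; MAE loss; 5000 epochs in batches of 5. `epsilon` stabilizes the
#' RMSProp denominator (an exactly-zero fuzz factor would make the first
#' step undefined, so a small positive default is used). The `"test"`
#' profile caps epochs at 500 for desk-scale runs.
#'
#' @param seed Integer seed for weight initialization.
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate RMSProp step size.
#' @param rho RMSProp gradient-decay rate.
#' @param epsilon RMSProp fuzz factor (small positive).
#' @param lr_decay Per-epoch learning-rate decay (0 = constant).
#' @param n_conv_layers,n_filters,kernel_size,conv_stride Conv stack shape.
#' @param pool_kind,pool_size,pool_stride Pooling layer.
#' @param profile `"full"` (the 5000-epoch reference budget) or `"test"`
#'   (epochs capped at 500 for desk-scale runs).
#' @return List of class `"cnn_config"`.
#' @export
cnn_config <- function(seed = 1L, epochs = 5000L, batch_size = 5L,
                       learning_rate = 0.001, rho = 0.9, epsilon = 1e-7,
                       lr_decay = 0, n_conv_layers = 5L, n_filters = 16L,
                       kernel_size = 3L, conv_stride = 1L,
                       pool_kind = c("max", "average"), pool_size = 2L,
                       pool_stride = 2L, profile = c("full", "test")) {
  pool_kind <- match.arg(pool_kind)
  profile <- match.arg(profile)
  if (profile == "test") epochs <- min(epochs, 500L)
  if (epochs < 1) fail("epochs must be >= 1")
  if (learning_rate < 0 || rho <= 0 || rho >= 1 || epsilon <= 0)
    fail("need learning_rate >= 0, 0 < rho < 1, epsilon > 0")
  if (conv_stride != 1L) fail("only conv stride 1 is supported")
  structure(list(seed = as.integer(seed), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 lr_decay = lr_decay, n_conv_layers = as.integer(n_conv_layers),
                 n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size),
                 conv_stride = as.integer(conv_stride),
                 pool_kind = pool_kind, pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride), profile = profile),
            class = "cnn_config")
}

# minimum input width consumable by the conv stack plus one pool window
min_input_width <- function(config) {
  config$n_conv_layers * (config$kernel_size - 1L) + config$pool_size
}

#' Rectified linear unit
#'
#' @param x Numeric vector, matrix or scalar.
#' @return Elementwise `max(0, x)`, same shape.
#' @export
relu <- function(x) pmax(x, 0)

# kernels array (out, in, k) -> flat weight matrix (out x in*k) with
# row-major (channel-major) kernel layout matching the C++ im2col
flatten_kernels <- function(kernels) {
  d <- dim(kernels)
  w <- matrix(0, d[1], d[2] * d[3])
  for (i in seq_len(d[2]))
    w[, (i - 1) * d[3] + seq_len(d[3])] <- kernels[, i, , drop = TRUE]
  w
}

#' Valid-padding 1-D convolution (cross-correlation) forward pass
#'
#' Output channel j at position p is
#' `bias[j] + sum_i sum_t kernels[j, i, t] * x[i, p + t - 1]` — the usual
#' cross-correlation convention with no padding and stride 1.
#'
#' @param x Input: numeric vector (one channel) or matrix (channels x width).
#' @param kernels Array of dim `(n_out, n_in, kernel_size)`.
#' @param bias Numeric vector of length `n_out`.
#' @return Matrix `(n_out x (width - kernel_size + 1))`.
#' @export
conv1d_forward <- function(x, kernels, bias = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (length(dim(kernels)) == 2)
    kernels <- array(kernels, c(nrow(kernels), 1, ncol(kernels)))
  d <- dim(kernels)
  if (d[2] != nrow(x))
    fail("kernels expect %d input channel(s) but x has %d", d[2], nrow(x))
  if (is.null(bias)) bias <- numeric(d[1])
  cpp_conv1d(x, flatten_kernels(kernels), bias, d[3])
}

#' 1-D pooling forward pass
#'
#' Windowed maximum or mean per channel; any trailing remainder narrower
#' than the window is dropped, so the output width is
#' `floor((W - size)/stride) + 1`.
#'
#' @param x Numeric vector (one channel) or matrix (channels x width).
#' @param kind `"max"` or `"average"`.
#' @param size Window length.
#' @param stride Step between windows.
#' @return Matrix of pooled values.
#' @export
pool1d <- function(x, kind = c("max", "average"), size = 2L, stride = 2L) {
  kind <- match.arg(kind)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (size < 1 || stride < 1) fail("pool size and stride must be >= 1")
  cpp_pool1d(x, as.integer(size), as.integer(stride), kind == "max")
}

#' Global average pooling
#'
#' @param x Matrix (channels x width) or vector (one channel).
#' @return One mean per channel.
#' @export
global_avg_pool <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) == 0) fail("cannot average an empty channel")
  rowMeans(x)
}

#' Dense (fully connected) forward pass with identity activation
#'
#' @param v Feature vector.
#' @param weights Weight vector of the same length.
#' @param bias Scalar bias.
#' @return `sum(weights * v) + bias`.
#' @export
dense_forward <- function(v, weights, bias = 0) {
  if (length(v) != length(weights))
    fail("feature vector length %d does not match weight length %d",
         length(v), length(weights))
  sum(weights * v) + bias
}

# Seeded uniform init scaled by fan-in: U(-s, s), s = 1/sqrt(fan_in).
init_cnn_params <- function(config, in_channels = 1L) {
  with_seed(config$seed, {
    k <- config$kernel_size
    nf <- config$n_filters
    conv_w <- list(); conv_b <- list()
    nin <- in_channels
    for (l in seq_len(config$n_conv_layers)) {
      s <- 1 / sqrt(nin * k)
      conv_w[[l]] <- matrix(runif(nf * nin * k, -s, s), nf, nin * k)
      conv_b[[l]] <- numeric(nf)
      nin <- nf
    }
    s <- 1 / sqrt(nf)
    list(conv_w = conv_w, conv_b = conv_b,
         dense_w = runif(nf, -s, s), dense_b = 0)
  })
}

check_cnn_width <- function(config, W) {
  if (W < min_input_width(config))
    fail("input width %d is below the minimum %d consumable by %d conv layers and pooling",
         W, min_input_width(config), config$n_conv_layers)
}

#' Forward pass of a (possibly untrained) CNN on standardized spectra
#'
#' Composition conv -> ReLU (x5) -> max pool -> global average pool ->
#' dense, on standardized inputs, returning standardized predictions.
#'
#' @param model A `trained_cnn` (or a list with `params` and `config`).
#' @param X Standardized spectra: numeric vector or matrix (rows = samples).
#' @return Numeric vector of standardized predictions.
#' @export
cnn_forward <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  cfg <- model$config
  check_cnn_width(cfg, ncol(X))
  as.numeric(cpp_cnn_forward(X, model$params, cfg$kernel_size, cfg$pool_size,
                             cfg$pool_stride, cfg$pool_kind == "max"))
}

#' Train the 1-D CNN
#'
#' Standardizes inputs and target (population-SD z-score; the scaler is
#' stored in the model for anti-normalization at prediction time),
#' initializes weights from the seeded RNG, and runs mini-batch RMSProp on
#' the MAE loss. Batches are contiguous fixed-order slices, so training is
#' exactly reproducible.
#'
#' @param X Numeric matrix of spectra (rows = samples) in original units.
#' @param y Numeric Fv/Fm targets in original units.
#' @param config A [cnn_config()].
#' @return Object of class `"trained_cnn"`: `params`, `config`, `scaler`,
#'   `history` (per-epoch mean training MAE, standardized units), `width`.
#' @export
train_cnn <- function(X, y, config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) fail("X and y disagree on the sample count")
  if (nrow(X) < config$batch_size)
    fail("need at least batch_size = %d samples, got %d",
         config$batch_size, nrow(X))
  check_cnn_width(config, ncol(X))
  scaler <- fit_standardizer(X, y)
  std <- apply_standardizer(scaler, X, y)
  params <- init_cnn_params(config)
  fit <- cpp_cnn_train(std$X, std$y, params, config$kernel_size,
                       config$pool_size, config$pool_stride,
                       config$pool_kind == "max", config$learning_rate,
                       config$rho, config$epsilon, config$lr_decay,
                       config$epochs, config$batch_size)
  # armadillo returns column vectors as n x 1 matrices; restore plain vectors
  fit$params$conv_b <- lapply(fit$params$conv_b, as.numeric)
  fit$params$dense_w <- as.numeric(fit$params$dense_w)
  structure(list(params = fit$params, config = config, scaler = scaler,
                 history = as.numeric(fit$history), width = ncol(X)),
            class = "trained_cnn")
}

#' @export
print.trained_cnn <- function(x, ...) {
  cat(sprintf("<trained_cnn> %d conv layers x %d filters, input width %d, %d epochs (final training MAE %.4g, standardized)\n",
              x$config$n_conv_layers, x$config$n_filters, x$width,
              length(x$history), utils::tail(x$history, 1)))
  invisible(x)
}

#' Predict Fv/Fm in original units
#'
#' Standardizes raw spectra with the scaler stored at training time, runs
#' the forward pass, and inverts the target standardization.
#'
#' @param model A [train_cnn()] model.
#' @param X Raw spectra matrix; the channel count must match training.
#' @return Numeric vector of predicted Fv/Fm values.
#' @export
predict_cnn <- function(model, X) {
  stopifnot(inherits(model, "trained_cnn"))
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$width)
    fail("spectra have %d channels but the model was trained on %d",
         ncol(X), model$width)
  Xs <- apply_standardizer(model$scaler, X)$X
  zs <- cnn_forward(model, Xs)
  invert_standardizer(model$scaler, y = zs)$y
}

#' @export
predict.trained_cnn <- function(object, newdata, ...) {
  predict_cnn(object, newdata)
}
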