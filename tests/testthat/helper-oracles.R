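# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive loops / direct least squares so they share no
# code path with the package internals they check.

# triple-loop valid cross-correlation: x (in_ch x W), kernels (out, in, k)
oracle_conv1d <- function(x, kernels, bias) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  d <- dim(kernels)
  L <- ncol(x) - d[3] + 1
  out <- matrix(0, d[1], L)
  for (j in seq_len(d[1]))
    for (p in seq_len(L)) {
      acc <- bias[j]
      for (i in seq_len(d[2]))
        for (t in seq_len(d[3]))
          acc <- acc + kernels[j, i, t] * x[i, p + t - 1]
      out[j, p] <- acc
    }
  out
}

oracle_pool1d <- function(x, kind, size, stride) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  L <- floor((ncol(x) - size) / stride) + 1
  out <- matrix(0, nrow(x), L)
  for (ch in seq_len(nrow(x)))
    for (p in seq_len(L)) {
      win <- x[ch, ((p - 1) * stride + 1):((p - 1) * stride + size)]
      out[ch, p] <- if (kind == "max") max(win) else mean(win)
    }
  out
}

# per-point Savitzky-Golay by explicit windowed polynomial regression
oracle_sg <- function(values, window, polyorder) {
  n <- length(values)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    c0 <- min(max(i, h + 1), n - h)  # window center (clamped at the edges)
    idx <- (c0 - h):(c0 + h)
    fit <- lm(values[idx] ~ poly(idx, degree = polyorder, raw = TRUE))
    out[i] <- as.numeric(predict(fit, data.frame(idx = i)))
  }
  out
}

# SPA chain via least-squares residuals: at each step regress every column
# on the already-selected (mean-centered) columns and pick the largest
# residual norm
oracle_spa_chain <- function(X, start, N) {
  Xc <- sweep(X, 2, colMeans(X))
  chain <- start
  while (length(chain) < N) {
    S <- Xc[, chain, drop = FALSE]
    norms <- vapply(seq_len(ncol(Xc)), function(j) {
      if (j %in% chain) return(-Inf)
      r <- stats::lsfit(S, Xc[, j], intercept = FALSE)$residuals
      sum(r^2)
    }, numeric(1))
    chain <- c(chain, which.max(norms))
  }
  chain
}

# exhaustive best single predictor column by validation RMSE
oracle_best_single_column <- function(Xcal, ycal, Xval, yval) {
  rmses <- vapply(seq_len(ncol(Xcal)), function(j) {
    fit <- lm(ycal ~ Xcal[, j])
    pred <- cbind(1, Xval[, j]) %*% coef(fit)
    sqrt(mean((yval - pred)^2))
  }, numeric(1))
  list(best = which.min(rmses), rmse = min(rmses))
}

# full CNN forward pass composed from the R-level oracle pieces
oracle_cnn_forward <- function(params, config, x) {
  A <- matrix(x, nrow = 1)
  k <- config$kernel_size
  for (l in seq_along(params$conv_w)) {
    w <- params$conv_w[[l]]
    nin <- nrow(A)
    kern <- array(0, c(nrow(w), nin, k))
    for (i in seq_len(nin)) kern[, i, ] <- w[, (i - 1) * k + seq_len(k)]
    A <- oracle_conv1d(A, kern, params$conv_b[[l]])
    A <- pmax(A, 0)
  }
  A <- oracle_pool1d(A, config$pool_kind, config$pool_size, config$pool_stride)
  sum(params$dense_w * rowMeans(A)) + params$dense_b
}

# small fast trial settings shared across tests (coarse 160-channel grid)
tp_small <- function(...) {
  trial_params(grid = seq(350, 2500, length.out = 160), ...)
}
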