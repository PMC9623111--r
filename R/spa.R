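# Successive Projections Algorithm (SPA) wavelength selection and the
# Kennard-Stone calibration/validation split.
#
# SPA builds, from a chosen start column, a chain of minimally collinear
# columns: each step picks the column with the largest norm orthogonal to
# the span of the columns already chosen. Candidate subsets (every start
# column, every chain length in [Nmin, Nmax]) are scored by ordinary
# least-squares regression on the calibration set, evaluated by RMSE on the
# validation set.

#' SPA projection chain
#'
#' Columns are mean-centered before projection. At each step the remaining
#' column with the maximal Euclidean norm of its component orthogonal to the
#' span of the already-selected columns is appended; ties break to the
#' lowest column index.
#'
#' @param X Numeric matrix (calibration block).
#' @param start Start column index (1-based).
#' @param N Chain length, `1 <= N <= min(nrow(X), ncol(X))`.
#' @return Integer vector of `N` column indices, beginning with `start`.
#' @export
spa_chain <- function(X, start, N) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (start < 1 || start > p) fail("start column %d out of range 1..%d", start, p)
  if (N < 1 || N > min(nrow(X), p))
    fail("chain length N = %d must lie in [1, min(n_rows, n_cols)] = [1, %d]",
         N, min(nrow(X), p))
  chain <- spa_chain_upto(X, start, N)
  if (length(chain) < N)
    fail("chain length N = %d exceeds the rank-feasible length (%d selected)",
         N, length(chain))
  chain
}

# Greedy chain of length at most N; stops early when no remaining column has
# a numerically nonzero orthogonal component.
spa_chain_upto <- function(X, start, N) {
  R <- sweep(X, 2, colMeans(X))  # residuals after projecting out selected cols
  chain <- as.integer(start)
  if (N == 1) return(chain)
  tol <- 1e-12 * max(1, sum(R^2))
  for (t in seq_len(N - 1)) {
    v <- R[, chain[t]]
    v2 <- sum(v^2)
    if (v2 > tol) R <- R - outer(v, as.numeric(crossprod(R, v)) / v2)
    norms <- colSums(R^2)
    norms[chain[seq_len(t)]] <- -Inf
    if (max(norms) <= tol) break
    chain <- c(chain, which.max(norms))  # which.max ties -> lowest index
  }
  chain
}

ols_val_rmse <- function(Xcal, ycal, Xval, yval, cols) {
  A <- cbind(1, Xcal[, cols, drop = FALSE])
  fit <- tryCatch(qr(A), error = function(e) NULL)
  if (is.null(fit) || fit$rank < ncol(A)) return(NA_real_)
  beta <- qr.coef(fit, ycal)
  pred <- cbind(1, Xval[, cols, drop = FALSE]) %*% beta
  sqrt(mean((yval - pred)^2))
}

#' SPA variable selection with MLR scoring
#'
#' Sweeps every start column (optionally a deterministic stride subsample)
#' and every chain length in `[Nmin, Nmax]`; each candidate subset is fitted
#' by OLS (with intercept) on the calibration set and scored by validation
#' RMSE. Rank-deficient candidate subsets are skipped with a log entry. The
#' minimal-RMSE subset wins; among equal-RMSE candidates the first in
#' (start, N) order is kept, so the result is deterministic.
#'
#' @param Xcal,ycal Calibration predictors and target.
#' @param Xval,yval Validation predictors and target.
#' @param Nmin,Nmax Bounds on the subset size,
#'   `Nmin <= Nmax <= min(nrow(Xcal) - 1, ncol(Xcal))`.
#' @param max_starts Optional cap on the number of start columns; starts are
#'   subsampled with a deterministic stride when capped.
#' @return Object of class `"selection_result"`: `indices` (ordered selected
#'   columns), `n_selected`, `validation_rmse` (per-candidate trace with
#'   start, size, rmse), `best_rmse`.
#' @export
spa_select <- function(Xcal, ycal, Xval, yval, Nmin = 1L, Nmax = 10L,
                       max_starts = NULL) {
  Xcal <- as.matrix(Xcal); Xval <- as.matrix(Xval)
  p <- ncol(Xcal)
  limit <- min(nrow(Xcal) - 1, p)
  if (Nmin < 1 || Nmin > Nmax || Nmax > limit)
    fail("need 1 <= Nmin <= Nmax <= min(n_rows - 1, n_cols) = %d", limit)
  if (ncol(Xval) != p) fail("calibration and validation column counts differ")
  starts <- seq_len(p)
  if (!is.null(max_starts) && max_starts < p)
    starts <- starts[seq(1, p, length.out = max_starts)] |> unique()
  trace <- list()
  best <- list(rmse = Inf, indices = integer(0))
  n_skipped <- 0L
  for (s in starts) {
    chain <- spa_chain_upto(Xcal, s, Nmax)
    if (length(chain) < Nmin) next
    for (N in Nmin:min(Nmax, length(chain))) {
      cols <- chain[seq_len(N)]
      rmse_v <- ols_val_rmse(Xcal, ycal, Xval, yval, cols)
      if (is.na(rmse_v)) {
        n_skipped <- n_skipped + 1L
        next
      }
      trace[[length(trace) + 1L]] <- data.frame(start = s, size = N,
                                                rmse = rmse_v)
      if (rmse_v < best$rmse) best <- list(rmse = rmse_v, indices = cols)
    }
  }
  if (!length(trace)) fail("no scoreable SPA candidate subsets")
  if (n_skipped > 0)
    message(sprintf("spa_select: skipped %d rank-deficient candidate subset(s)",
                    n_skipped))
  structure(list(indices = best$indices,
                 n_selected = length(best$indices),
                 validation_rmse = do.call(rbind, trace),
                 best_rmse = best$rmse),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d column(s): %s (validation RMSE %.6g)\n",
              x$n_selected, paste(x$indices, collapse = ", "), x$best_rmse))
  invisible(x)
}

#' Kennard-Stone calibration/validation split
#'
#' Picks the maximally distant pair first, then repeatedly adds the point
#' maximizing its minimum Euclidean distance to the points already picked.
#' Fully deterministic; ties break to the lowest row index.
#'
#' @param X Numeric matrix of samples (rows).
#' @param fraction Calibration fraction in (0, 1); calibration size is
#'   `round(n * fraction)`, at least 2.
#' @return List with integer vectors `calibration` and `validation`.
#' @export
kennard_stone_split <- function(X, fraction = 0.75) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) fail("Kennard-Stone needs at least 2 samples")
  if (fraction <= 0 || fraction >= 1) fail("fraction must lie in (0, 1)")
  n_cal <- max(2L, min(n, as.integer(round(n * fraction))))
  D <- as.matrix(dist(X))
  # farthest pair, lowest indices on ties
  flat <- which(D == max(D), arr.ind = TRUE)
  pair <- sort(flat[order(flat[, 1], flat[, 2]), , drop = FALSE][1, ])
  picked <- as.integer(pair)
  mind <- pmin(D[, picked[1]], D[, picked[2]])
  while (length(picked) < n_cal) {
    mind[picked] <- -Inf
    nxt <- which.max(mind)
    picked <- c(picked, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  list(calibration = picked, validation = setdiff(seq_len(n), picked))
}
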