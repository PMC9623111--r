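# Model evaluation: the four chemometric error metrics and the
# deterministic sorted train/test split.

check_pred_pair <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    fail("y_true (%d) and y_pred (%d) differ in length",
         length(y_true), length(y_pred))
  if (length(y_true) < 1) fail("need at least one prediction")
  if (anyNA(y_true) || anyNA(y_pred)) fail("missing values in predictions")
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y_true Observed values (not constant, n >= 2).
#' @param y_pred Predicted values.
#' @return R-squared (<= 1; negative when worse than the mean predictor).
#' @export
r2 <- function(y_true, y_pred) {
  check_pred_pair(y_true, y_pred)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (length(y_true) < 2 || ss_tot == 0)
    fail("R^2 is undefined for a constant y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root mean square error
#' @inheritParams r2
#' @return `sqrt(mean((y - yhat)^2))`, target units.
#' @export
rmse <- function(y_true, y_pred) {
  check_pred_pair(y_true, y_pred)
  sqrt(mean((y_true - y_pred)^2))
}

#' Mean absolute error
#' @inheritParams r2
#' @return `mean(|y - yhat|)`, target units.
#' @export
mae <- function(y_true, y_pred) {
  check_pred_pair(y_true, y_pred)
  mean(abs(y_true - y_pred))
}

#' Mean absolute percentage error
#'
#' `(100/n) * sum(|(yhat - y)/y|)`, in percent. Undefined when any observed
#' value is zero.
#'
#' @inheritParams r2
#' @return MAPE in percent.
#' @export
mape <- function(y_true, y_pred) {
  check_pred_pair(y_true, y_pred)
  if (any(y_true == 0)) fail("MAPE is undefined when y_true contains zeros")
  100 * mean(abs((y_pred - y_true) / y_true))
}

#' All four metrics at once
#' @inheritParams r2
#' @return Named list with `r2`, `rmse`, `mae`, `mape`.
#' @export
eval_metrics <- function(y_true, y_pred) {
  list(r2 = r2(y_true, y_pred), rmse = rmse(y_true, y_pred),
       mae = mae(y_true, y_pred), mape = mape(y_true, y_pred))
}

#' Deterministic sorted train/test split
#'
#' Rows are sorted by `sample_id`; the first `floor(n * fraction)` form the
#' training set and the remainder the test set, so shuffled input yields an
#' identical split. An optional shuffle seed permutes samples before the
#' prefix cut for randomized robustness studies.
#'
#' @param dm A [to_design_matrix()] object.
#' @param fraction Training fraction in (0, 1), default 0.75.
#' @param shuffle_seed Optional integer; when given, the sorted rows are
#'   permuted with this seed before the cut.
#' @return List with `train` and `test`, each a `design_matrix`.
#' @export
split_train_test <- function(dm, fraction = 0.75, shuffle_seed = NULL) {
  stopifnot(inherits(dm, "design_matrix"))
  if (fraction <= 0 || fraction >= 1) fail("fraction must lie in (0, 1)")
  n <- nrow(dm$X)
  if (n < 2) fail("need at least 2 samples to split")
  ord <- order(dm$meta$sample_id)
  if (!is.null(shuffle_seed)) ord <- with_seed(shuffle_seed, sample(ord))
  n_train <- floor(n * fraction)
  if (n_train < 1 || n_train >= n)
    fail("fraction %.3f leaves an empty train or test side for n = %d",
         fraction, n)
  take <- function(idx) {
    meta <- dm$meta[idx, , drop = FALSE]
    rownames(meta) <- NULL
    structure(list(X = dm$X[idx, , drop = FALSE], y = dm$y[idx],
                   meta = meta, grid = dm$grid),
              class = "design_matrix")
  }
  list(train = take(ord[seq_len(n_train)]),
       test = take(ord[seq(n_train + 1, n)]))
}
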