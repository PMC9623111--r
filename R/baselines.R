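# Uniform interface over the classical comparator regressors. These models
# are comparators, not the package's contribution, so established library
# implementations are called throughout; models whose backing library is
# not installed are reported as skipped rather than re-implemented.

BASELINE_NAMES <- c("CatBoost", "LightGBM", "XGBoost", "DT", "RF", "GBDT",
                    "AdaBoost", "ET", "KNN")

baseline_backend <- function(name) {
  switch(name,
         DT = "rpart", RF = "randomForest", ET = "ranger", KNN = "caret",
         XGBoost = "xgboost", GBDT = "xgboost",
         CatBoost = NA_character_, LightGBM = NA_character_,
         AdaBoost = NA_character_)
}

#' Baseline model specification
#'
#' @param name One of `r paste(BASELINE_NAMES, collapse = ", ")`.
#' @param hyperparameters Named list overriding the backend defaults.
#' @param seed Integer seed for stochastic fitters.
#' @return List of class `"baseline_spec"`.
#' @export
baseline_spec <- function(name, hyperparameters = list(), seed = 1L) {
  if (!name %in% BASELINE_NAMES)
    fail("unknown baseline '%s'; must be one of %s", name,
         paste(BASELINE_NAMES, collapse = ", "))
  structure(list(name = name, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

hp <- function(spec, key, default) {
  v <- spec$hyperparameters[[key]]
  if (is.null(v)) default else v
}

#' Fit one comparator regressor
#'
#' Dispatches to the backing library: decision tree (`rpart`), random
#' forest (`randomForest`), extremely randomized trees (`ranger` with the
#' extratrees split rule), k-nearest neighbours (`caret::knnreg`), and
#' gradient boosting (`xgboost`; the `GBDT` entry runs it as plain exact
#' greedy gradient boosting without column subsampling). CatBoost, LightGBM
#' and AdaBoost have no installed backend here and are skipped with a log
#' entry, as is any model whose backing package is unavailable.
#'
#' @param spec A [baseline_spec()].
#' @param X Numeric predictor matrix.
#' @param y Numeric target.
#' @return Object of class `"baseline_model"` exposing `predict()`, or
#'   `NULL` (with a message) when the model is skipped.
#' @export
fit_baseline <- function(spec, X, y) {
  stopifnot(inherits(spec, "baseline_spec"))
  X <- as.matrix(X)
  if (nrow(X) < 2) fail("need at least 2 training samples")
  backend <- baseline_backend(spec$name)
  if (is.na(backend) || !requireNamespace(backend, quietly = TRUE)) {
    message(sprintf("baseline %s skipped: backing library %s unavailable",
                    spec$name, if (is.na(backend)) "(none in R)" else backend))
    return(NULL)
  }
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  fit <- with_seed(spec$seed, switch(
    spec$name,
    DT = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(
                     minsplit = hp(spec, "minsplit", 2),
                     minbucket = hp(spec, "minbucket", 1),
                     cp = hp(spec, "cp", 0), xval = 0,
                     maxdepth = hp(spec, "maxdepth", 30)))
    },
    RF = randomForest::randomForest(x = X, y = y,
                                    ntree = hp(spec, "ntree", 500)),
    ET = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      ranger::ranger(.y ~ ., data = df, splitrule = "extratrees",
                     num.random.splits = hp(spec, "num.random.splits", 1),
                     replace = FALSE, sample.fraction = 1,
                     num.trees = hp(spec, "num.trees", 500),
                     seed = spec$seed, num.threads = 1)
    },
    KNN = caret::knnreg(X, y, k = hp(spec, "k", 5)),
    XGBoost = xgboost::xgboost(X, y, objective = "reg:squarederror",
                               nrounds = hp(spec, "nrounds", 100),
                               learning_rate = hp(spec, "eta", 0.3),
                               max_depth = hp(spec, "max_depth", 6),
                               nthreads = 1, seed = spec$seed),
    GBDT = xgboost::xgboost(X, y, objective = "reg:squarederror",
                            nrounds = hp(spec, "nrounds", 100),
                            learning_rate = hp(spec, "eta", 0.1),
                            max_depth = hp(spec, "max_depth", 3),
                            reg_lambda = 0, reg_alpha = 0,
                            tree_method = "exact", colsample_bytree = 1,
                            subsample = 1, nthreads = 1, seed = spec$seed)
  ))
  structure(list(name = spec$name, spec = spec, fit = fit,
                 n_features = ncol(X)),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    fail("newdata has %d features but the model was fitted on %d",
         ncol(newdata), object$n_features)
  colnames(newdata) <- paste0("x", seq_len(ncol(newdata)))
  switch(object$name,
         DT = as.numeric(predict(object$fit,
                                 data.frame(newdata, check.names = FALSE))),
         ET = as.numeric(predict(object$fit,
                                 data.frame(newdata, check.names = FALSE),
                                 num.threads = 1)$predictions),
         XGBoost = ,
         GBDT = as.numeric(predict(object$fit, newdata)),
         as.numeric(predict(object$fit, newdata)))
}

hyper_string <- function(model) {
  sp <- model$spec
  defaults <- switch(model$name,
                     DT = "rpart: minsplit=2, minbucket=1, cp=0",
                     RF = "randomForest: ntree=500",
                     ET = "ranger: extratrees, num.trees=500, replace=FALSE",
                     KNN = "caret::knnreg: k=5",
                     XGBoost = "xgboost: nrounds=100, eta=0.3, max_depth=6",
                     GBDT = "xgboost(exact): nrounds=100, eta=0.1, max_depth=3",
                     "")
  extra <- if (length(sp$hyperparameters))
    paste(";", paste(names(sp$hyperparameters), unlist(sp$hyperparameters),
                     sep = "=", collapse = ", ")) else ""
  paste0(defaults, extra)
}

#' Comparison table across baseline models, stages and treatments
#'
#' For every treatment x stage cell present in the trial, splits the
#' design matrix 75/25 (deterministic sorted split), fits each requested
#' model on the training side, and reports held-out RMSE, MAE and MAPE —
#' one row per model x condition x stage. Hyperparameters are echoed into
#' the table for provenance. Models whose backend is unavailable are
#' logged and omitted.
#'
#' @param set A [spectra_set] of predictors.
#' @param physiology Data frame with `sample_id` and `fvfm_true` (or
#'   `fvfm`) targets.
#' @param models Character vector of baseline names, or `"all"`.
#' @param fraction Training fraction (default 0.75).
#' @param seed Integer seed forwarded to every fitter.
#' @return Data frame with columns `model`, `treatment`, `stage`, `rmse`,
#'   `mae`, `mape`, `n_train`, `n_test`, `hyperparameters`.
#' @export
compare_models <- function(set, physiology, models = "all", fraction = 0.75,
                           seed = 1L) {
  stopifnot(inherits(set, "spectra_set"))
  if (identical(models, "all")) models <- BASELINE_NAMES
  tcol <- if ("fvfm_true" %in% names(physiology)) "fvfm_true" else "fvfm"
  targets <- stats::setNames(physiology[[tcol]], physiology$sample_id)
  rows <- list()
  for (tr in intersect(c("CK", "DS"), unique(set$meta$treatment))) {
    for (st in intersect(STAGES, unique(set$meta$stage))) {
      idx <- set$meta$treatment == tr & set$meta$stage == st
      if (!any(idx)) next
      dm <- to_design_matrix(subset_spectra(set, idx), targets)
      parts <- split_train_test(dm, fraction)
      for (mname in models) {
        model <- fit_baseline(baseline_spec(mname, seed = seed),
                              parts$train$X, parts$train$y)
        if (is.null(model)) next
        pred <- predict(model, parts$test$X)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mname, treatment = tr, stage = st,
          rmse = rmse(parts$test$y, pred),
          mae = mae(parts$test$y, pred),
          mape = mape(parts$test$y, pred),
          n_train = length(parts$train$y), n_test = length(parts$test$y),
          hyperparameters = hyper_string(model),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) fail("no model x condition x stage cells produced results")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
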