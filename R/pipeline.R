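# End-to-end orchestration: simulate (or load) -> preprocess -> optional
# SPA diagnostics -> CNN training -> evaluation -> tolerance ranking, with
# every artifact written under one run directory and a manifest that fully
# determines the run.

#' Pipeline run configuration
#'
#' One global seed expands deterministically into per-stage seeds
#' (simulation, training, baselines). When `spectra_path` is given the trial
#' is read from disk (spectral table plus physiology CSV); otherwise a
#' synthetic trial is generated with `trial` parameters.
#'
#' @param out_dir Run directory; created if missing.
#' @param seed Global integer seed.
#' @param G Number of genotypes for a simulated trial.
#' @param trial A [trial_params()] object.
#' @param stages Stages to simulate/use.
#' @param cnn A [cnn_config()]; its seed is overridden by the expanded
#'   per-stage seed.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param fraction Training fraction for the sorted split.
#' @param stage Stage used for the tolerance ranking.
#' @param topk Size of the reported top list.
#' @param baselines Character vector of baseline names (possibly empty).
#' @param spa Logical: run the SPA selection diagnostic (on a stride-capped
#'   start sweep).
#' @param spectra_path,physiology_path Optional input files for a real
#'   (non-simulated) trial.
#' @return List of class `"run_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, G = 20L,
                            trial = trial_params(), stages = "flowering",
                            cnn = cnn_config(profile = "test"),
                            sg_window = 11L, sg_polyorder = 2L,
                            fraction = 0.75, stage = "flowering", topk = 10L,
                            baselines = character(0), spa = FALSE,
                            spectra_path = NULL, physiology_path = NULL) {
  check_stage(stages); check_stage(stage)
  if (!stage %in% stages) fail("ranking stage '%s' is not among the run stages", stage)
  structure(list(out_dir = out_dir, seed = as.integer(seed), G = as.integer(G),
                 trial = trial, stages = stages, cnn = cnn,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 fraction = fraction, stage = stage, topk = as.integer(topk),
                 baselines = baselines, spa = isTRUE(spa),
                 spectra_path = spectra_path,
                 physiology_path = physiology_path),
            class = "run_config")
}

stage_seeds <- function(seed) {
  list(simulate = seed, train = seed + 1000L, baselines = seed + 2000L,
       spa = seed + 3000L)
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Stages: obtain the trial (simulate or load), Savitzky-Golay smooth the
#' spectra, optionally run the SPA wavelength-selection diagnostic, split
#' 75/25 on sorted sample ids, train the 1-D CNN on the training side,
#' predict Fv/Fm for every sample, evaluate on the held-out side, compute
#' measured and predicted drought-tolerance coefficient tables at the
#' ranking stage, cluster them, and write `manifest.json`, `metrics.json`,
#' `predictions.csv`, `ranking.json` (and `comparison.csv` when baselines
#' are requested) under the run directory. Identical configuration and seed
#' reproduce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage banners.
#' @return Invisibly, a list with the trial, model, metrics, DTC tables,
#'   concordance report and file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  # fail before any compute if declared inputs are absent
  for (p in c(config$spectra_path, config$physiology_path))
    if (!is.null(p) && !file.exists(p)) fail("input path does not exist: %s", p)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)

  log_stage(quiet, "stage: trial (%s)",
            if (is.null(config$spectra_path)) "simulate" else "load")
  if (is.null(config$spectra_path)) {
    panel <- make_genotypes(config$G, seed = seeds$simulate)
    trial <- simulate_trial(panel, config$trial, seed = seeds$simulate,
                            stages = config$stages)
    tau <- panel$tau
  } else {
    spectra <- read_spectra_table(config$spectra_path)
    phys <- read.csv(config$physiology_path, stringsAsFactors = FALSE)
    trial <- list(spectra = spectra, physiology = phys)
    tau <- NULL
  }

  log_stage(quiet, "stage: preprocess (S-G window %d, order %d)",
            config$sg_window, config$sg_polyorder)
  smoothed <- smooth_spectra(trial$spectra, config$sg_window,
                             config$sg_polyorder)
  targets <- stats::setNames(trial$physiology$fvfm_true,
                             trial$physiology$sample_id)
  dm <- to_design_matrix(smoothed, targets)

  selection <- NULL
  if (config$spa) {
    log_stage(quiet, "stage: SPA diagnostic")
    ks <- kennard_stone_split(dm$X, 0.75)
    selection <- with_seed(seeds$spa,
      spa_select(dm$X[ks$calibration, ], dm$y[ks$calibration],
                 dm$X[ks$validation, ], dm$y[ks$validation],
                 Nmin = 1L, Nmax = 10L, max_starts = 32L))
  }

  log_stage(quiet, "stage: train CNN (%d epochs)", config$cnn$epochs)
  parts <- split_train_test(dm, config$fraction)
  cnn_cfg <- config$cnn
  cnn_cfg$seed <- seeds$train
  model <- train_cnn(parts$train$X, parts$train$y, cnn_cfg)

  log_stage(quiet, "stage: evaluate")
  pred_test <- predict_cnn(model, parts$test$X)
  metrics <- eval_metrics(parts$test$y, pred_test)
  pred_all <- predict_cnn(model, dm$X)

  comparison <- NULL
  if (length(config$baselines)) {
    log_stage(quiet, "stage: baselines (%s)",
              paste(config$baselines, collapse = ", "))
    comparison <- compare_models(smoothed, trial$physiology,
                                 models = config$baselines,
                                 fraction = config$fraction,
                                 seed = seeds$baselines)
  }

  log_stage(quiet, "stage: rank (stage %s, top %d)", config$stage, config$topk)
  meas_rec <- data.frame(genotype_id = dm$meta$genotype_id,
                         treatment = dm$meta$treatment,
                         stage = dm$meta$stage, fvfm = dm$y)
  pred_rec <- transform(meas_rec, fvfm = pred_all)
  dtc_meas <- dtc_table(meas_rec, stage = config$stage, source = "measured")
  dtc_pred <- dtc_table(pred_rec, stage = config$stage, source = "predicted")
  concord <- rank_and_compare(dtc_meas, dtc_pred, k = config$topk)
  clust_meas <- cluster_dtc(dtc_meas)
  clust_pred <- cluster_dtc(dtc_pred)

  # ---- artifacts -----------------------------------------------------
  paths <- list(manifest = file.path(config$out_dir, "manifest.json"),
                metrics = file.path(config$out_dir, "metrics.json"),
                predictions = file.path(config$out_dir, "predictions.csv"),
                ranking = file.path(config$out_dir, "ranking.json"),
                comparison = file.path(config$out_dir, "comparison.csv"),
                selection = file.path(config$out_dir, "selection.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fvfmspec")),
    seed = config$seed, stage_seeds = seeds, G = config$G,
    stages = config$stages, fraction = config$fraction,
    ranking_stage = config$stage, topk = config$topk,
    sg = list(window = config$sg_window, polyorder = config$sg_polyorder),
    cnn = unclass(cnn_cfg),
    trial = unclass(config$trial)[setdiff(names(unclass(config$trial)), "grid")],
    grid = list(n = length(config$trial$grid),
                min = min(config$trial$grid), max = max(config$trial$grid)),
    baselines = config$baselines, spa = config$spa)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write.csv(data.frame(dm$meta, fvfm_measured = dm$y,
                       fvfm_predicted = pred_all),
            paths$predictions, row.names = FALSE)
  ranking_out <- list(
    stage = config$stage, k = concord$k,
    topk_measured = concord$topk_measured,
    topk_predicted = concord$topk_predicted,
    overlap = concord$overlap, spearman_rho = concord$spearman_rho,
    dtc_measured = dtc_meas[c("genotype_id", "dtc")],
    dtc_predicted = dtc_pred[c("genotype_id", "dtc")])
  jsonlite::write_json(ranking_out, paths$ranking, digits = NA, pretty = TRUE)
  if (!is.null(comparison))
    write.csv(comparison, paths$comparison, row.names = FALSE)
  if (!is.null(selection))
    jsonlite::write_json(list(indices = selection$indices,
                              wavelengths = dm$grid[selection$indices],
                              best_rmse = selection$best_rmse,
                              trace = selection$validation_rmse),
                         paths$selection, digits = NA, pretty = TRUE)
  log_stage(quiet, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  invisible(list(trial = trial, tau = tau, model = model, metrics = metrics,
                 predictions = pred_all, dm = dm, split = parts,
                 dtc_measured = dtc_meas, dtc_predicted = dtc_pred,
                 concordance = concord, clusters_measured = clust_meas,
                 clusters_predicted = clust_pred, comparison = comparison,
                 selection = selection, paths = paths))
}
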