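#!/usr/bin/env Rscript
# Stage 4 — Fv/Fm prediction: 1D-CNN vs classical regressors.
#
# Trains the five-conv-layer 1D-CNN on the flowering-stage 75% split
# (desk-scale budget: 200 RMSProp epochs, MAE loss) and evaluates R2, RMSE,
# MAE and MAPE on the held-out 25%. Then regenerates a comparison table of
# the available classical regressors per treatment x stage cell.

suppressMessages(library(fvfmspec))

seed <- 2026L
clean <- read_spectra_table("results/trial_spectra_clean.csv")
phys <- read.csv("results/trial_physiology.csv")
targets <- setNames(phys$fvfm_true, phys$sample_id)

flowering <- subset_spectra(clean, clean$meta$stage == "flowering")
dm <- to_design_matrix(flowering, targets)
parts <- split_train_test(dm, 0.75)

cat(sprintf("training 1D-CNN on %d samples x %d channels...\n",
            nrow(parts$train$X), ncol(parts$train$X)))
model <- train_cnn(parts$train$X, parts$train$y,
                   cnn_config(seed = seed, epochs = 200L, profile = "test"))
pred <- predict_cnn(model, parts$test$X)
m <- eval_metrics(parts$test$y, pred)
cat(sprintf("1D-CNN held-out: R2 = %.3f, RMSE = %.5f, MAE = %.5f, MAPE = %.3f%%\n",
            m$r2, m$rmse, m$mae, m$mape))
cat(sprintf("training loss fell from %.3f (epoch 1) to %.3f (final, standardized MAE)\n",
            model$history[1], tail(model$history, 1)))

pred_all <- predict_cnn(model, dm$X)
write.csv(data.frame(dm$meta, fvfm_measured = dm$y, fvfm_predicted = pred_all),
          "results/cnn_predictions_flowering.csv", row.names = FALSE)
jsonlite::write_json(m, "results/cnn_metrics_flowering.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("fitting classical regressors per treatment x stage cell...\n")
comparison <- compare_models(clean, phys,
                             models = c("XGBoost", "DT", "RF", "GBDT",
                                        "ET", "KNN"),
                             fraction = 0.75, seed = seed)
write.csv(comparison, "results/model_comparison.csv", row.names = FALSE)
best <- aggregate(rmse ~ treatment + stage, data = comparison, FUN = min)
cat("lowest classical-regressor RMSE per cell:\n")
print(transform(best, rmse = signif(rmse, 3)), row.names = FALSE)
cat("wrote results/model_comparison.csv, cnn_predictions_flowering.csv, cnn_metrics_flowering.json\n")
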