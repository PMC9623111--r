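#!/usr/bin/env Rscript
# Stage 3 — SPA wavelength-selection diagnostic.
#
# Runs the successive projections algorithm on the flowering-stage spectra
# with a Kennard-Stone calibration/validation split, scoring subsets of 1-10
# wavelengths by MLR validation RMSE. The start-column sweep is capped with
# a deterministic stride (32 starts over 1024 channels) to keep the sweep
# tractable. The pipeline default remains full-spectrum modeling; this stage
# documents how few minimally collinear wavelengths SPA finds informative.

suppressMessages(library(fvfmspec))

clean <- read_spectra_table("results/trial_spectra_clean.csv")
phys <- read.csv("results/trial_physiology.csv")
targets <- setNames(phys$fvfm_true, phys$sample_id)

flowering <- subset_spectra(clean, clean$meta$stage == "flowering")
dm <- to_design_matrix(flowering, targets)
ks <- kennard_stone_split(dm$X, 0.75)
sel <- spa_select(dm$X[ks$calibration, ], dm$y[ks$calibration],
                  dm$X[ks$validation, ], dm$y[ks$validation],
                  Nmin = 1L, Nmax = 10L, max_starts = 32L)

cat(sprintf("SPA selected %d wavelength(s): %s nm (validation RMSE %.5f)\n",
            sel$n_selected,
            paste(round(dm$grid[sel$indices]), collapse = ", "),
            sel$best_rmse))
best_by_size <- aggregate(rmse ~ size, data = sel$validation_rmse, FUN = min)
cat("best validation RMSE by subset size:\n")
print(transform(best_by_size, rmse = signif(rmse, 4)), row.names = FALSE)

jsonlite::write_json(list(indices = sel$indices,
                          wavelengths_nm = dm$grid[sel$indices],
                          best_rmse = sel$best_rmse,
                          rmse_by_size = best_by_size),
                     "results/spa_selection.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/spa_selection.json\n")
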