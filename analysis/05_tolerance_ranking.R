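#!/usr/bin/env Rscript
# Stage 5 — drought-tolerance coefficients, clustering, and concordance.
#
# Converts measured and CNN-predicted Fv/Fm into per-genotype drought
# tolerance coefficients (mean DS / mean CK) at the flowering stage, ranks
# genotypes, clusters the coefficients (Ward linkage), and quantifies how
# well the predicted ranking reproduces the measured one — including how
# both track the generator's latent tolerance.

suppressMessages(library(fvfmspec))

pred <- read.csv("results/cnn_predictions_flowering.csv")
tau <- read.csv("results/latent_tolerance.csv")

rec_meas <- data.frame(genotype_id = pred$genotype_id,
                       treatment = pred$treatment, stage = pred$stage,
                       fvfm = pred$fvfm_measured)
rec_pred <- transform(rec_meas, fvfm = pred$fvfm_predicted)
dtc_meas <- dtc_table(rec_meas, "flowering", "measured")
dtc_pred <- dtc_table(rec_pred, "flowering", "predicted")

concord <- rank_and_compare(dtc_meas, dtc_pred, k = 10L)
cl_meas <- cluster_dtc(dtc_meas, k = 3)
cl_pred <- cluster_dtc(dtc_pred, k = 3)

cat("top-10 drought-tolerant genotypes (measured): ",
    paste(concord$topk_measured, collapse = ", "), "\n")
cat("top-10 drought-tolerant genotypes (predicted):",
    paste(concord$topk_predicted, collapse = ", "), "\n")
cat(sprintf("top-10 overlap: %d/10; Spearman rho (measured vs predicted DTC): %.3f\n",
            concord$overlap, concord$spearman_rho))
cat(sprintf("Spearman rho (latent tau vs measured DTC):  %.3f\n",
            cor(tau$tau, dtc_meas$dtc, method = "spearman")))
cat(sprintf("Spearman rho (latent tau vs predicted DTC): %.3f\n",
            cor(tau$tau, dtc_pred$dtc, method = "spearman")))

jsonlite::write_json(
  list(k = concord$k,
       topk_measured = concord$topk_measured,
       topk_predicted = concord$topk_predicted,
       overlap = concord$overlap,
       spearman_rho = concord$spearman_rho,
       dtc_measured = dtc_meas[c("genotype_id", "dtc")],
       dtc_predicted = dtc_pred[c("genotype_id", "dtc")],
       clusters_measured = as.list(cl_meas$labels),
       clusters_predicted = as.list(cl_pred$labels)),
  "results/tolerance_ranking.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

# dendrogram of the measured DTC clustering, exportable as Newick
if (requireNamespace("ape", quietly = TRUE)) {
  phy <- ape::as.phylo(cl_meas$tree)
  ape::write.tree(phy, "results/dtc_dendrogram_measured.nwk")
  cat("wrote results/dtc_dendrogram_measured.nwk\n")
}
cat("wrote results/tolerance_ranking.json\n")
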