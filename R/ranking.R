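# Physiological formulas, drought-tolerance coefficients, hierarchical
# clustering of genotypes, and measured-vs-predicted ranking concordance.

#' Maximum photochemical quantum yield of PSII
#'
#' `Fv/Fm = (Fm - Fo)/Fm` from the dark-adapted initial (Fo) and maximal
#' (Fm) fluorescence.
#'
#' @param Fo Initial fluorescence (arbitrary units), `0 <= Fo <= Fm`.
#' @param Fm Maximal fluorescence (> 0).
#' @return Fv/Fm in `[0, 1]` (vectorized).
#' @export
fvfm <- function(Fo, Fm) {
  if (any(Fm <= 0)) fail("Fm must be positive")
  if (any(Fo < 0) || any(Fo > Fm)) fail("need 0 <= Fo <= Fm")
  (Fm - Fo) / Fm
}

#' Gravimetric water content
#'
#' `100 * (fresh - dry) / fresh`, in percent.
#'
#' @param fresh Fresh weight (g), > 0.
#' @param dry Dry weight (g), `0 < dry <= fresh`.
#' @return Water content in percent (vectorized).
#' @export
water_content <- function(fresh, dry) {
  if (any(dry <= 0) || any(fresh <= 0)) fail("weights must be positive")
  if (any(dry > fresh)) fail("dry weight exceeds fresh weight")
  100 * (fresh - dry) / fresh
}

#' Per-genotype drought tolerance coefficients
#'
#' For each genotype the DTC is the mean Fv/Fm under drought divided by the
#' mean under control at the chosen stage: `DTC = mean(DS) / mean(CK)`.
#' Higher values indicate stronger drought tolerance.
#'
#' @param records Data frame with columns `genotype_id`, `treatment`
#'   (CK/DS), `stage`, and `fvfm` (measured or predicted values).
#' @param stage Stage at which to compute the table (default flowering, the
#'   stage used for the headline ranking).
#' @param source Label recording whether the values are `"measured"` or
#'   `"predicted"`.
#' @return Object of class `"dtc_table"`: data frame with `genotype_id`,
#'   `mean_fvfm_CK`, `mean_fvfm_DS`, `dtc`, `n_CK`, `n_DS`, sorted by
#'   genotype, with the source label as attribute `"source"`.
#' @export
dtc_table <- function(records, stage = "flowering",
                      source = c("measured", "predicted")) {
  source <- match.arg(source)
  check_stage(stage)
  need <- c("genotype_id", "treatment", "fvfm", "stage")
  miss <- setdiff(need, names(records))
  if (length(miss)) fail("records missing column(s): %s",
                         paste(miss, collapse = ", "))
  rec <- records[records$stage == stage, , drop = FALSE]
  if (!nrow(rec)) fail("no records at stage '%s'", stage)
  gids <- sort(unique(rec$genotype_id))
  agg <- function(tr) {
    sub <- rec[rec$treatment == tr, , drop = FALSE]
    list(mean = tapply(sub$fvfm, factor(sub$genotype_id, levels = gids), mean),
         n = tapply(sub$fvfm, factor(sub$genotype_id, levels = gids), length))
  }
  ck <- agg("CK"); ds <- agg("DS")
  bad <- gids[is.na(ck$mean) | is.na(ds$mean)]
  if (length(bad))
    fail("genotype(s) missing a treatment arm at stage '%s': %s", stage,
         paste(bad, collapse = ", "))
  out <- data.frame(genotype_id = gids,
                    mean_fvfm_CK = as.numeric(ck$mean),
                    mean_fvfm_DS = as.numeric(ds$mean),
                    dtc = as.numeric(ds$mean) / as.numeric(ck$mean),
                    n_CK = as.integer(ck$n), n_DS = as.integer(ds$n))
  rownames(out) <- NULL
  structure(out, class = c("dtc_table", "data.frame"), source = source,
            stage = stage)
}

#' Rank genotypes by drought tolerance coefficient
#'
#' Descending DTC; ties break to the lower genotype id.
#'
#' @param table A [dtc_table()].
#' @return Integer vector of genotype ids, most tolerant first.
#' @export
dtc_ranking <- function(table) {
  stopifnot(inherits(table, "dtc_table"))
  table$genotype_id[order(-table$dtc, table$genotype_id)]
}

#' Hierarchical clustering of drought tolerance coefficients
#'
#' Agglomerative clustering (Ward linkage by default) on the Euclidean
#' distance between scalar DTC values, with an optional cut into `k`
#' clusters, plus the descending-DTC ranking.
#'
#' @param table A [dtc_table()] with at least 2 genotypes.
#' @param k Optional number of clusters for the cut.
#' @param method Linkage passed to [stats::hclust()] (default `"ward.D2"`).
#' @return Object of class `"cluster_result"`: the `hclust` tree (`tree`),
#'   `merge`/`height`, `labels` (genotype -> cluster, if `k` given), and
#'   `ranking`.
#' @export
cluster_dtc <- function(table, k = NULL, method = "ward.D2") {
  stopifnot(inherits(table, "dtc_table"))
  if (nrow(table) < 2) fail("clustering needs at least 2 genotypes")
  d <- dist(table$dtc)
  attr(d, "Labels") <- as.character(table$genotype_id)
  tree <- hclust(d, method = method)
  labels <- NULL
  if (!is.null(k)) {
    cl <- cutree(tree, k = k)
    labels <- stats::setNames(as.integer(cl), as.character(table$genotype_id))
  }
  structure(list(tree = tree, merge = tree$merge, height = tree$height,
                 labels = labels, ranking = dtc_ranking(table),
                 method = method),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d genotypes, %s linkage%s\n",
              length(x$ranking), x$method,
              if (is.null(x$labels)) "" else
                sprintf(", %d clusters", length(unique(x$labels)))))
  cat("top of ranking:", paste(utils::head(x$ranking, 10), collapse = ", "), "\n")
  invisible(x)
}

#' Concordance between measured and predicted tolerance rankings
#'
#' Compares two DTC tables over the same genotypes: size of the top-k
#' intersection and Spearman rank correlation (average ranks on ties) over
#' all genotypes.
#'
#' @param measured,predicted [dtc_table()] objects over identical genotype
#'   sets.
#' @param k Top-list size (default 10).
#' @return List of class `"concordance_report"`: `topk_measured`,
#'   `topk_predicted`, `overlap`, `spearman_rho`, `k`.
#' @export
rank_and_compare <- function(measured, predicted, k = 10L) {
  stopifnot(inherits(measured, "dtc_table"), inherits(predicted, "dtc_table"))
  if (!identical(sort(measured$genotype_id), sort(predicted$genotype_id)))
    fail("measured and predicted tables cover different genotype sets")
  k <- min(as.integer(k), nrow(measured))
  m <- measured[order(measured$genotype_id), ]
  p <- predicted[order(predicted$genotype_id), ]
  top_m <- utils::head(dtc_ranking(measured), k)
  top_p <- utils::head(dtc_ranking(predicted), k)
  structure(list(topk_measured = top_m, topk_predicted = top_p,
                 overlap = length(intersect(top_m, top_p)),
                 spearman_rho = cor(m$dtc, p$dtc, method = "spearman"),
                 k = k),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance> top-%d overlap %d/%d, Spearman rho %.3f\n",
              x$k, x$overlap, x$k, x$spearman_rho))
  invisible(x)
}
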