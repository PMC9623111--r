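test_that("Fv/Fm and water-content formulas are exact and guarded", {
  expect_equal(fvfm(0.3, 1.5), 0.8)
  expect_equal(fvfm(1.5, 1.5), 0)
  expect_equal(fvfm(0, 2), 1)
  expect_error(fvfm(0.5, 0), "positive")
  expect_error(fvfm(2, 1), "Fo")

  expect_equal(water_content(10, 2), 80)
  expect_equal(water_content(5, 5), 0)
  expect_equal(water_content(4, 3), 25)
  expect_error(water_content(2, 3), "exceeds")
  expect_error(water_content(2, 0), "positive")
})

toy_records <- function() {
  data.frame(genotype_id = rep(1:3, each = 6),
             treatment = rep(rep(c("CK", "DS"), each = 3), 3),
             stage = "flowering",
             fvfm = c(0.80, 0.81, 0.79, 0.76, 0.75, 0.77,   # g1
                      0.82, 0.80, 0.81, 0.80, 0.81, 0.82,   # g2
                      0.78, 0.78, 0.78, 0.60, 0.62, 0.58))  # g3
}

test_that("DTC tables are per-genotype DS/CK mean ratios", {
  rec <- toy_records()
  tab <- dtc_table(rec, "flowering")
  # spreadsheet-style oracle: group means and their ratio
  for (g in 1:3) {
    ck <- mean(rec$fvfm[rec$genotype_id == g & rec$treatment == "CK"])
    ds <- mean(rec$fvfm[rec$genotype_id == g & rec$treatment == "DS"])
    expect_equal(tab$dtc[tab$genotype_id == g], ds / ck, tolerance = 1e-12)
  }
  expect_equal(tab$n_CK, rep(3L, 3))
  # forced examples
  one <- data.frame(genotype_id = 1, treatment = c("CK", "DS"),
                    stage = "flowering", fvfm = c(0.80, 0.76))
  expect_equal(dtc_table(one)$dtc, 0.95)
  same <- transform(one, fvfm = 0.8)
  expect_equal(dtc_table(same)$dtc, 1)
  # genotypes missing an arm are listed
  broken <- rec[!(rec$genotype_id == 2 & rec$treatment == "DS"), ]
  expect_error(dtc_table(broken), "2")
})

test_that("DTC is invariant to rescaling a genotype's fluorescence values", {
  rec <- toy_records()
  tab1 <- dtc_table(rec)
  rec2 <- rec
  idx <- rec2$genotype_id == 2
  rec2$fvfm[idx] <- rec2$fvfm[idx] * 0.9
  tab2 <- dtc_table(rec2)
  expect_equal(tab2$dtc, tab1$dtc, tolerance = 1e-12)
})

test_that("Ward clustering of DTC values recovers the planted partition", {
  tab <- structure(data.frame(genotype_id = 1:4,
                              mean_fvfm_CK = 0.8, mean_fvfm_DS = NA,
                              dtc = c(0.99, 0.98, 0.60, 0.61),
                              n_CK = 3L, n_DS = 3L),
                   class = c("dtc_table", "data.frame"))
  cl <- cluster_dtc(tab, k = 2)
  # exhaustive 2-partition oracle on 4 points: minimal within-cluster
  # variance split is {1,2} vs {3,4}
  expect_equal(unname(cl$labels[1]), unname(cl$labels[2]))
  expect_equal(unname(cl$labels[3]), unname(cl$labels[4]))
  expect_false(cl$labels[1] == cl$labels[3])
  # merge heights are monotone for Ward linkage
  expect_true(all(diff(cl$height) >= -1e-12))
  # ranking is by descending dtc
  expect_equal(cl$ranking, c(1, 2, 4, 3))
  # identical dtc values collapse into one chain without error
  tied <- tab; tied$dtc <- rep(0.9, 4)
  expect_s3_class(cluster_dtc(tied, k = 2), "cluster_result")
  # permuting genotypes relabels but does not change the partition
  perm <- tab[c(3, 1, 4, 2), ]
  clp <- cluster_dtc(perm, k = 2)
  expect_equal(unname(clp$labels[as.character(1:2)]),
               rep(unname(clp$labels["1"]), 2))
  expect_error(cluster_dtc(tab[1, ], k = 1), "at least 2")
})

test_that("ranking concordance reports overlap and Spearman rho", {
  tab <- function(dtc) structure(data.frame(genotype_id = seq_along(dtc),
                                            mean_fvfm_CK = 0.8,
                                            mean_fvfm_DS = NA, dtc = dtc,
                                            n_CK = 3L, n_DS = 3L),
                                 class = c("dtc_table", "data.frame"))
  m <- tab(c(0.99, 0.95, 0.90, 0.85))
  expect_s3_class(m, "dtc_table")
  same <- rank_and_compare(m, m, k = 4)
  expect_equal(same$overlap, 4)
  expect_equal(same$spearman_rho, 1)
  rev_ <- rank_and_compare(m, tab(rev(m$dtc)), k = 4)
  expect_equal(rev_$spearman_rho, -1)
  # ranks (1,2,3,4) vs (2,1,3,4): rho = 1 - 6*2/(4*15) = 0.8, overlap 2
  swapped <- rank_and_compare(m, tab(c(0.95, 0.99, 0.90, 0.85)), k = 2)
  expect_equal(swapped$overlap, 2)
  expect_equal(swapped$spearman_rho, 0.8)
  other <- tab(c(0.9, 0.8, 0.7))
  expect_error(rank_and_compare(m, other), "different genotype sets")
})

test_that("with default noise the measured ranking tracks tau closely", {
  panel <- make_genotypes(40, seed = 77)
  ph <- simulate_fvfm(panel, tp_small(), seed = 77)
  ph$fvfm <- ph$fvfm_true
  tab <- dtc_table(ph, stage = "flowering")
  expect_gte(cor(panel$tau, tab$dtc, method = "spearman"), 0.8)
})
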