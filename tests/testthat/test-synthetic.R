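test_that("genotype panels are seeded, bounded, and reproducible", {
  p1 <- make_genotypes(80, seed = 7)
  p2 <- make_genotypes(80, seed = 7)
  expect_identical(p1$tau, p2$tau)
  expect_length(p1$tau, 80)
  expect_true(min(p1$tau) >= 0 && max(p1$tau) <= 1)
  expect_false(identical(make_genotypes(5, 1)$tau, make_genotypes(5, 2)$tau))
  expect_error(make_genotypes(0), ">= 1")
})

test_that("drought reduces Fv/Fm by stage_max_drop * (1 - tau) before noise", {
  params <- tp_small(fvfm_noise_sd = 0, water_noise_sd = 0)
  # fully tolerant genotype: DS record equals CK record
  panel <- make_genotypes(1, seed = 1)
  panel$tau <- 1
  ph <- simulate_fvfm(panel, params, seed = 1)
  ck <- ph[ph$treatment == "CK", c("Fo", "Fm", "fvfm_true", "rwc", "lwc")]
  ds <- ph[ph$treatment == "DS", c("Fo", "Fm", "fvfm_true", "rwc", "lwc")]
  expect_equal(unname(as.matrix(ck)), unname(as.matrix(ds)))

  # fully susceptible genotype at the most sensitive stage: 12% reduction
  panel$tau <- 0
  ph <- simulate_fvfm(panel, params, seed = 1)
  ck2 <- ph$fvfm_true[ph$treatment == "CK" & ph$stage == "boll_setting"][1]
  ds2 <- ph$fvfm_true[ph$treatment == "DS" & ph$stage == "boll_setting"][1]
  expect_equal(ds2, 0.88 * ck2, tolerance = 1e-12)

  # Fo/Fm reproduce the generated Fv/Fm exactly
  expect_equal((ph$Fm - ph$Fo) / ph$Fm, ph$fvfm_true, tolerance = 1e-12)
  expect_true(all(ph$Fo > 0 & ph$Fo < ph$Fm))
})

test_that("stage means rise from flowering to boll setting then fall", {
  panel <- make_genotypes(40, seed = 11)
  ph <- simulate_fvfm(panel, tp_small(), seed = 11)
  m <- tapply(ph$fvfm_true, ph$stage, mean)[STAGES]
  expect_gt(m["boll_setting"], m["flowering"])
  expect_gt(m["flowering"], m["boll_opening"])
})

test_that("simulated spectra carry the documented optical landmarks", {
  params <- tp_small(spectral_noise_sd = 0)
  wl <- params$grid
  sp <- simulate_spectrum(0.8, 0.3, params, seed = 1)
  v <- sp$values
  in_band <- function(lo, hi) wl >= lo & wl <= hi
  # green peak: the visible-region maximum sits in 520-580 nm
  vis <- in_band(400, 700)
  expect_true(wl[vis][which.max(v[vis])] >= 520 &&
              wl[vis][which.max(v[vis])] <= 580)
  # absorption valleys inside 370-510 and 600-710 nm
  blue <- in_band(360, 520)
  expect_true(wl[blue][which.min(v[blue])] >= 370 &&
              wl[blue][which.min(v[blue])] <= 510)
  red <- in_band(590, 720)
  expect_true(wl[red][which.min(v[red])] >= 600 &&
              wl[red][which.min(v[red])] <= 710)
  # water band at 1450 nm sits strictly below the plateau at 1250 nm
  expect_lt(v[which.min(abs(wl - 1450))], v[which.min(abs(wl - 1250))])
  expect_lt(v[which.min(abs(wl - 1950))], v[which.min(abs(wl - 1750))])
  # all values are valid reflectance
  expect_true(all(v >= 0 & v <= 1))
})

test_that("stress raises the green peak and lowers the NIR plateau at equal Fv/Fm", {
  params <- tp_small(spectral_noise_sd = 0)
  wl <- params$grid
  calm <- simulate_spectrum(0.8, 0, params, seed = 1)$values
  stressed <- simulate_spectrum(0.8, 0.5, params, seed = 1)$values
  at <- function(v, nm) v[which.min(abs(wl - nm))]
  expect_gt(at(stressed, 550), at(calm, 550))
  expect_lt(at(stressed, 1000), at(calm, 1000))
  # NIR plateau amplitude increases with Fv/Fm
  lo <- simulate_spectrum(0.6, 0, params, seed = 1)$values
  hi <- simulate_spectrum(0.9, 0, params, seed = 1)$values
  expect_gt(at(hi, 1000), at(lo, 1000))
  # determinism
  expect_identical(simulate_spectrum(0.8, 0.5, params, seed = 9)$values,
                   simulate_spectrum(0.8, 0.5, params, seed = 9)$values)
})

test_that("trials have the full factorial layout and are byte-reproducible", {
  panel <- make_genotypes(10, seed = 5)
  params <- tp_small()
  tr1 <- simulate_trial(panel, params, seed = 5)
  expect_equal(n_samples(tr1$spectra), 10 * 2 * 3 * 3)
  expect_identical(tr1$spectra$meta$sample_id, tr1$physiology$sample_id)
  tr2 <- simulate_trial(panel, params, seed = 5)
  expect_identical(tr1$spectra$values, tr2$spectra$values)
  expect_identical(tr1$physiology, tr2$physiology)
  # all emitted spectra satisfy the reflectance invariants
  expect_true(all(tr1$spectra$values >= 0 & tr1$spectra$values <= 1))
})

test_that("Fv/Fm correlates positively with leaf water content", {
  panel <- make_genotypes(40, seed = 21)
  ph <- simulate_fvfm(panel, tp_small(), seed = 21)
  expect_gt(cor(ph$fvfm_true, ph$lwc, method = "spearman"), 0)
  expect_gt(cor(ph$fvfm_true, ph$rwc, method = "spearman"), 0)
})

test_that("the planted ranking signal is recovered exactly at zero noise", {
  panel <- make_genotypes(50, seed = 31)
  params <- tp_small(fvfm_noise_sd = 0, water_noise_sd = 0)
  ph <- simulate_fvfm(panel, params, seed = 31)
  ph$fvfm <- ph$fvfm_true
  tab <- dtc_table(ph, stage = "boll_setting", source = "measured")
  expect_gte(cor(panel$tau, tab$dtc, method = "spearman"), 0.99)
  # ranking by dtc equals ranking by tau
  expect_identical(dtc_ranking(tab), order(-panel$tau))
})
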