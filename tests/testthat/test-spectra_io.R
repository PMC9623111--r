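test_that("SVC ASCII parsing extracts radiance pairs and the percent column", {
  f <- withr::local_tempfile(lines = c("400 10 5 50", "401 10 6 60", "402 10 7 70"))
  rec <- read_svc_ascii(f)
  expect_equal(rec$percent, c(0.5, 0.6, 0.7))
  expect_equal(rec$target$values / rec$reference$values, c(0.5, 0.6, 0.7))
  expect_equal(rec$reference$wavelengths, c(400, 401, 402))
  expect_identical(rec$target$value_kind, "radiance")

  # banner + comment lines are skipped and do not change the result
  g <- withr::local_tempfile(lines = c("SVC HR-1024i field file", "# date: x",
                                       "400 10 5 50", "401 10 6 60",
                                       "402 10 7 70"))
  expect_equal(read_svc_ascii(g), rec)

  # malformed row is reported with its line number
  h <- withr::local_tempfile(lines = c("400 10 5 50", "401 10 6", "402 10 7 70"))
  expect_error(read_svc_ascii(h), "line 2")

  # wavelengths must ascend
  d <- withr::local_tempfile(lines = c("402 10 5 50", "401 10 6 60"))
  expect_error(read_svc_ascii(d), "increasing")
})

test_that("spectrum invariants are enforced", {
  expect_error(spectrum(c(400, 400, 401), c(0.1, 0.2, 0.3)), "increasing")
  expect_error(spectrum(c(400, 401), c(0.1, 0.2, 0.3)), "length")
  expect_error(spectrum(c(400, 401), c(0.1, 1.6)), "1.5")
  expect_warning(spectrum(c(400, 401), c(0.1, 1.2)), "overshoot")
  # radiance is not range-limited
  expect_silent(spectrum(c(400, 401), c(120, 130), "radiance"))
})

make_toy_set <- function(n = 2, wl = c(400, 450, 500, 550, 600)) {
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                     genotype_id = seq_len(n), treatment = "CK",
                     stage = "flowering", replicate = 1L)
  spectra_set(wl, meta, matrix(runif(n * length(wl), 0.1, 0.9), n))
}

test_that("spectral tables round-trip through CSV", {
  set.seed(42)
  set <- make_toy_set(2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(set, f)
  back <- read_spectra_table(f)
  expect_equal(back$grid, set$grid)
  expect_equal(back$values, set$values, tolerance = 1e-6)
  expect_equal(back$meta, set$meta)

  # empty set -> header-only file
  empty <- subset_spectra(set, integer(0))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(empty, f2)
  expect_length(readLines(f2), 1L)

  # a 1024-channel grid yields 1024 value columns
  wide <- spectra_set(default_grid(),
                      data.frame(sample_id = "a", genotype_id = 1,
                                 treatment = "CK", stage = "flowering",
                                 replicate = 1L),
                      matrix(0.5, 1, 1024))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(wide, f3)
  header <- strsplit(readLines(f3, n = 1), ",")[[1]]
  expect_length(header, 5 + 1024)
})

test_that("duplicate sample keys and bad headers are rejected", {
  meta <- data.frame(sample_id = c("a", "b"), genotype_id = 1,
                     treatment = "CK", stage = "flowering", replicate = 1L)
  expect_error(spectra_set(c(400, 500), meta, matrix(0.5, 2, 2)),
               "duplicate.*1/CK/flowering/1")
  f <- withr::local_tempfile(lines = c("sample_id,genotype_id,treatment,stage,replicate,400,notanumber",
                                       "a,1,CK,flowering,1,0.5,0.6"))
  expect_error(read_spectra_table(f), "non-numeric wavelength")
})

test_that("design matrices align targets in sorted-id order", {
  set.seed(7)
  set <- make_toy_set(3)
  set$meta$sample_id <- c("c", "a", "b")  # deliberately unsorted
  targets <- c(a = 0.8, b = 0.7, c = 0.75)
  dm <- to_design_matrix(set, targets)
  expect_equal(dm$y, c(0.8, 0.7, 0.75))
  expect_equal(dm$meta$sample_id, c("a", "b", "c"))
  expect_equal(dm$X[1, ], set$values[2, ])

  # permutation invariance
  perm <- subset_spectra(set, c(3, 1, 2))
  expect_equal(to_design_matrix(perm, targets), dm)

  # missing target is reported by id
  expect_error(to_design_matrix(set, targets[c("a", "b")]), "c")
})

test_that("a full-size generated trial yields the expected design shape", {
  panel <- make_genotypes(27, seed = 3)
  trial <- simulate_trial(panel, trial_params(n_replicates = 1L),
                          seed = 3, stages = "flowering")
  # 27 genotypes x 2 treatments x 1 replicate at one stage = 54 spectra
  targets <- stats::setNames(trial$physiology$fvfm_true,
                             trial$physiology$sample_id)
  dm <- to_design_matrix(trial$spectra, targets)
  expect_equal(dim(dm$X), c(54, 1024))
  expect_equal(nrow(dm$meta), length(dm$y))
})
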