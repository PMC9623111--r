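# Synthetic multi-genotype drought trials.
#
# A latent per-genotype tolerance value tau in [0,1] drives both physiology
# (the drought-induced Fv/Fm drop shrinks as tau -> 1) and leaf optics (the
# same latent stress raises visible reflectance at the green peak and lowers
# the near-infrared plateau). This plants a known ranking signal so the
# downstream prediction/ranking stages can be validated against ground truth.

#' Default wavelength grid
#'
#' 1024 channels spanning 350-2500 nm, the span and channel count of a
#' full-range field spectroradiometer.
#' @return Numeric vector of 1024 wavelengths (nm).
#' @export
default_grid <- function() seq(350, 2500, length.out = 1024)

#' Create a genotype panel with latent drought-tolerance values
#'
#' @param G Number of genotypes (>= 1).
#' @param seed Integer seed; the panel is reproducible given `(G, seed)`.
#' @return List of class `"genotype_panel"` with `G`, `tau` (uniform on
#'   `[0,1]`, one per genotype), and `seed`.
#' @export
make_genotypes <- function(G, seed = 1L) {
  if (!is.numeric(G) || length(G) != 1 || G < 1)
    fail("G must be a single integer >= 1")
  G <- as.integer(G)
  tau <- with_seed(seed, runif(G))
  structure(list(G = G, tau = tau, seed = as.integer(seed)),
            class = "genotype_panel")
}

#' Trial generation parameters
#'
#' Defaults encode the drought-trial structure the pipeline is designed for:
#' stage-baseline Fv/Fm rises from flowering to boll setting then falls at
#' boll opening, and the maximal drought-induced reduction (for a fully
#' susceptible genotype, tau = 0) is 2%, 12% and 3% at the three stages.
#' Because tau is uniform on `[0,1]`, population-mean reductions are half of
#' those maxima.
#'
#' @param stage_baseline_fvfm Fv/Fm baselines for flowering, boll setting,
#'   boll opening (dimensionless, in (0,1)).
#' @param stage_max_drop Fractional Fv/Fm reduction under drought at tau = 0
#'   per stage, in `[0,1)`.
#' @param fvfm_noise_sd SD of additive noise on each Fv/Fm record
#'   (dimensionless).
#' @param spectral_noise_sd SD of additive per-channel reflectance noise.
#' @param water_noise_sd SD of additive noise on root/leaf water content
#'   (percentage points).
#' @param n_replicates Replicates per genotype x treatment x stage.
#' @param grid Wavelength grid (nm), within 350-2500.
#' @param fm_level Maximum fluorescence Fm in arbitrary instrument units;
#'   held fixed so the zero-noise generator is an exact function of
#'   `(tau, params)`.
#' @return List of class `"trial_params"`.
#' @export
trial_params <- function(stage_baseline_fvfm = c(0.78, 0.83, 0.76),
                         stage_max_drop = c(0.02, 0.12, 0.03),
                         fvfm_noise_sd = 0.003,
                         spectral_noise_sd = 0.005,
                         water_noise_sd = 3,
                         n_replicates = 3L,
                         grid = default_grid(),
                         fm_level = 1500) {
  stopifnot(length(stage_baseline_fvfm) == 3, length(stage_max_drop) == 3)
  if (any(stage_baseline_fvfm <= 0) || any(stage_baseline_fvfm >= 1))
    fail("stage baselines must lie in (0, 1)")
  if (any(stage_max_drop < 0) || any(stage_max_drop >= 1))
    fail("stage_max_drop must lie in [0, 1)")
  if (fvfm_noise_sd < 0 || spectral_noise_sd < 0 || water_noise_sd < 0)
    fail("noise standard deviations must be >= 0")
  if (min(grid) < 350 || max(grid) > 2500)
    fail("grid must lie within the 350-2500 nm instrument range")
  structure(list(stage_baseline_fvfm = stats::setNames(stage_baseline_fvfm, STAGES),
                 stage_max_drop = stats::setNames(stage_max_drop, STAGES),
                 fvfm_noise_sd = fvfm_noise_sd,
                 spectral_noise_sd = spectral_noise_sd,
                 water_noise_sd = water_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 grid = as.numeric(grid),
                 fm_level = fm_level),
            class = "trial_params")
}

sample_ident <- function(genotype_id, treatment, stage, replicate) {
  sprintf("g%03d_%s_s%d_r%d", genotype_id, treatment,
          match(stage, STAGES), replicate)
}

# Noise-free Fv/Fm for one cell of the factorial
fvfm_mean_cell <- function(params, tau_g, treatment, stage) {
  base <- params$stage_baseline_fvfm[[stage]]
  if (treatment == "CK") return(base)
  base * (1 - params$stage_max_drop[[stage]] * (1 - tau_g))
}

#' Simulate per-sample fluorescence and water-content physiology
#'
#' One record is produced per genotype x treatment x stage x replicate.
#' Control (CK) records fluctuate around the stage baseline; drought (DS)
#' records are reduced by `stage_max_drop * (1 - tau_g)` before noise. Fo and
#' Fm are chosen so that `(Fm - Fo)/Fm` equals the generated Fv/Fm exactly,
#' and root/leaf water contents are increasing affine functions of Fv/Fm
#' plus noise, reproducing the positive Fv/Fm-water-content correlation.
#'
#' @param panel A [make_genotypes()] panel.
#' @param params A [trial_params()] object.
#' @param seed Integer seed.
#' @param stages Subset of [STAGES] to simulate (default all three).
#' @return Data frame with one row per record: sample metadata, `Fo`, `Fm`,
#'   `fvfm_true`, `rwc`, `lwc`.
#' @export
simulate_fvfm <- function(panel, params = trial_params(), seed = 1L,
                          stages = STAGES) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(params, "trial_params"))
  check_stage(stages)
  design <- expand.grid(replicate = seq_len(params$n_replicates),
                        stage = stages,
                        treatment = c("CK", "DS"),
                        genotype_id = seq_len(panel$G),
                        stringsAsFactors = FALSE)
  with_seed(seed, {
    mu <- mapply(function(g, tr, st) fvfm_mean_cell(params, panel$tau[g], tr, st),
                 design$genotype_id, design$treatment, design$stage)
    fvfm <- pmin(pmax(mu + params$fvfm_noise_sd * rnorm(nrow(design)), 1e-6),
                 1 - 1e-6)
    Fm <- rep(params$fm_level, nrow(design))
    Fo <- Fm * (1 - fvfm)
    rwc <- pmin(pmax(40 + 60 * fvfm + params$water_noise_sd * rnorm(nrow(design)), 0), 100)
    lwc <- pmin(pmax(45 + 50 * fvfm + params$water_noise_sd * rnorm(nrow(design)), 0), 100)
    data.frame(sample_id = sample_ident(design$genotype_id, design$treatment,
                                        design$stage, design$replicate),
               genotype_id = design$genotype_id,
               treatment = design$treatment,
               stage = design$stage,
               replicate = design$replicate,
               Fo = Fo, Fm = Fm, fvfm_true = fvfm, rwc = rwc, lwc = lwc,
               stringsAsFactors = FALSE)
  })
}

# Deterministic (noise-free) leaf reflectance curve. Shape: visible floor
# with a blue shoulder rising toward 350 nm, a stress-sensitive green peak
# at 550 nm, a chlorophyll red absorption dip at 670 nm that deepens in
# healthy leaves, a logistic red edge at ~715 nm up to a near-infrared
# plateau whose amplitude grows with Fv/Fm and shrinks with stress, a slow
# shortwave-infrared decline, and multiplicative water-absorption dips at
# 1450 and 1950 nm.
reflectance_base_curve <- function(wl, fvfm, stress) {
  vis <- 0.08 +
    0.04 * exp(-((wl - 350) / 60)^2) +
    (0.06 + 0.10 * stress) * exp(-((wl - 550) / 30)^2) -
    (0.02 + 0.03 * (1 - stress)) * exp(-((wl - 670) / 35)^2)
  r_nir <- 0.25 + 0.45 * fvfm - 0.10 * stress
  nir <- r_nir * (0.55 + 0.45 / (1 + exp((wl - 1500) / 180)))
  nir <- nir * (1 - 0.35 * exp(-((wl - 1450) / 35)^2)) *
    (1 - 0.55 * exp(-((wl - 1950) / 45)^2))
  edge <- 1 / (1 + exp(-(wl - 715) / 15))
  vis * (1 - edge) + nir * edge
}

#' Simulate one leaf reflectance spectrum
#'
#' @param fvfm Fv/Fm of the leaf (dimensionless, in `[0,1]`).
#' @param stress Latent drought-stress severity in `[0,1]` (0 for
#'   well-watered).
#' @param params A [trial_params()] object (grid and spectral noise SD).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A reflectance [spectrum] on `params$grid`, clipped to `[0,1]`.
#' @export
simulate_spectrum <- function(fvfm, stress, params = trial_params(),
                              seed = NULL) {
  stopifnot(inherits(params, "trial_params"))
  if (fvfm < 0 || fvfm > 1) fail("fvfm must lie in [0, 1]")
  if (stress < 0 || stress > 1) fail("stress must lie in [0, 1]")
  gen <- function() {
    r <- reflectance_base_curve(params$grid, fvfm, stress) +
      params$spectral_noise_sd * rnorm(length(params$grid))
    spectrum(params$grid, pmin(pmax(r, 0), 1), "reflectance")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Stress severity used for the optical model: the stage drop rescaled so the
# most drought-prone stage at tau = 0 maps to stress = 1; CK is stress 0.
stress_level <- function(params, tau_g, treatment, stage) {
  if (treatment == "CK") return(0)
  s <- params$stage_max_drop[[stage]] / max(params$stage_max_drop)
  s * (1 - tau_g)
}

#' Simulate a complete trial: paired spectra and physiology
#'
#' @inheritParams simulate_fvfm
#' @return List with `spectra` (a [spectra_set]) and `physiology` (the
#'   [simulate_fvfm()] data frame), one spectrum per physiology record.
#' @export
simulate_trial <- function(panel, params = trial_params(), seed = 1L,
                           stages = STAGES) {
  stopifnot(inherits(panel, "genotype_panel"))
  phys <- simulate_fvfm(panel, params, seed = seed, stages = stages)
  values <- with_seed(seed + 1L, {
    t(vapply(seq_len(nrow(phys)), function(i) {
      s <- stress_level(params, panel$tau[phys$genotype_id[i]],
                        phys$treatment[i], phys$stage[i])
      simulate_spectrum(phys$fvfm_true[i], s, params, seed = NULL)$values
    }, numeric(length(params$grid))))
  })
  set <- spectra_set(params$grid,
                     phys[, c("sample_id", "genotype_id", "treatment",
                              "stage", "replicate")],
                     values)
  list(spectra = set, physiology = phys)
}
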