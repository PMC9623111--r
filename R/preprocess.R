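# Spectral preprocessing: Savitzky-Golay smoothing, reference-panel
# reflectance calibration, grid resampling, replicate averaging, and a
# reversible standardizer whose state is retained for anti-normalization of
# model predictions.

#' Savitzky-Golay smoothing (or differentiation)
#'
#' Local least-squares polynomial filtering: each interior point is replaced
#' by the value of the degree-`polyorder` polynomial fitted over the
#' centered window; the terminal half-windows are handled by evaluating the
#' polynomial fitted to the first/last full window at the edge positions, so
#' the output has the same length as the input. Exact on polynomial series
#' up to degree `polyorder`.
#'
#' @param values Numeric vector, length >= `window`.
#' @param window Odd window length >= 3 (samples).
#' @param polyorder Polynomial degree, `0 <= polyorder < window`.
#' @param derivative Derivative order (0 = smoothing). Derivatives are with
#'   respect to the sample index (unit spacing).
#' @return Numeric vector of the same length as `values`.
#' @export
savitzky_golay <- function(values, window = 11L, polyorder = 2L,
                           derivative = 0L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window < 3 || window %% 2 == 0)
    fail("window must be an odd integer >= 3, got %d", window)
  if (polyorder < 0 || polyorder >= window)
    fail("polyorder must satisfy 0 <= polyorder < window")
  if (derivative < 0 || derivative > polyorder)
    fail("derivative order must lie in [0, polyorder]")
  if (length(values) < window)
    fail("series length %d is shorter than the window %d",
         length(values), window)
  as.numeric(signal::sgolayfilt(as.numeric(values), p = polyorder,
                                n = window, m = derivative, ts = 1))
}

#' Smooth every spectrum in a set
#'
#' Applies [savitzky_golay()] row-wise to a [spectra_set].
#'
#' @param set A [spectra_set].
#' @inheritParams savitzky_golay
#' @return A [spectra_set] with smoothed values, clipped to `[0, 1.5]` to
#'   respect the reflectance invariant.
#' @export
smooth_spectra <- function(set, window = 11L, polyorder = 2L,
                           derivative = 0L) {
  stopifnot(inherits(set, "spectra_set"))
  sm <- t(apply(set$values, 1, savitzky_golay, window = window,
                polyorder = polyorder, derivative = derivative))
  if (derivative == 0) sm <- pmin(pmax(sm, 0), 1.5)
  spectra_set(set$grid, set$meta, sm)
}

#' Reference-panel reflectance calibration
#'
#' Converts target radiance to reflectance against a reference panel:
#' `Rt = (L / Lr) * Rr` channel by channel.
#'
#' @param L Target radiance (numeric vector).
#' @param Lr Reference radiance, same length, strictly positive.
#' @param Rr Reference-panel reflectance: scalar or same-length vector.
#' @return Reflectance vector `Rt`.
#' @export
calibrate_reflectance <- function(L, Lr, Rr) {
  if (length(L) != length(Lr))
    fail("L (%d) and Lr (%d) differ in length", length(L), length(Lr))
  if (length(Rr) == 1) Rr <- rep(Rr, length(L))
  if (length(Rr) != length(L))
    fail("Rr must be a scalar or match the radiance length")
  bad <- which(Lr <= 0)
  if (length(bad))
    fail("non-positive reference radiance at channel(s): %s",
         paste(utils::head(bad, 5), collapse = ", "))
  (L / Lr) * Rr
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation between bracketing source points; exact where the
#' grids coincide. Extrapolation outside the source span is refused.
#'
#' @param spec A [spectrum].
#' @param grid Target wavelengths (nm), within the source span.
#' @return A [spectrum] on the target grid.
#' @export
resample_to_grid <- function(spec, grid) {
  stopifnot(inherits(spec, "spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(spec$wavelengths) || max(grid) > max(spec$wavelengths))
    fail("target grid [%g, %g] extends beyond the source span [%g, %g]; extrapolation is not supported",
         min(grid), max(grid), min(spec$wavelengths), max(spec$wavelengths))
  vals <- approx(spec$wavelengths, spec$values, xout = grid,
                 method = "linear", rule = 1)$y
  spectrum(grid, vals, spec$value_kind)
}

#' Average replicate spectra
#'
#' Collapses a [spectra_set] to one arithmetic-mean curve per unique
#' combination of the grouping keys (replicate sample points averaged into a
#' leaf-level spectrum, or replicates into a plot mean).
#'
#' @param set A [spectra_set].
#' @param keys Metadata columns defining the groups.
#' @return A [spectra_set] with one row per group; `replicate` is collapsed
#'   to 1 and `sample_id` rebuilt from the keys.
#' @export
average_replicates <- function(set, keys = c("genotype_id", "treatment", "stage")) {
  stopifnot(inherits(set, "spectra_set"))
  if (n_samples(set) == 0) fail("cannot average an empty spectra set")
  if (!all(keys %in% names(set$meta)))
    fail("unknown grouping key(s): %s",
         paste(setdiff(keys, names(set$meta)), collapse = ", "))
  grp <- interaction(set$meta[keys], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(n_samples(set)), grp)
  values <- t(vapply(idx, function(i) colMeans(set$values[i, , drop = FALSE]),
                     numeric(length(set$grid))))
  meta <- set$meta[vapply(idx, `[`, integer(1), 1), , drop = FALSE]
  meta$replicate <- 1L
  meta$sample_id <- vapply(seq_along(idx), function(j) {
    paste(unlist(meta[j, keys]), collapse = "_")
  }, character(1))
  spectra_set(set$grid, meta, values)
}

#' Fit a reversible standardizer
#'
#' Centers every feature column and the target on their means and divides by
#' their population standard deviation (the `n` divisor, matching the usual
#' machine-learning scaler). Constant columns receive scale 1 so they map to
#' zero without a division error. The state is kept so predictions can be
#' mapped back to original units.
#'
#' @param X Numeric matrix (n >= 2 rows).
#' @param y Optional numeric target vector.
#' @param divide_by `"sd"` (default, z-score) or `"variance"` (literal
#'   division by the variance).
#' @return Object of class `"scaler"` with per-feature `center`/`scale` and,
#'   if `y` was given, `y_center`/`y_scale`.
#' @export
fit_standardizer <- function(X, y = NULL, divide_by = c("sd", "variance")) {
  divide_by <- match.arg(divide_by)
  X <- as.matrix(X)
  if (nrow(X) < 2) fail("standardizer needs at least 2 rows")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  center <- colMeans(X)
  spread <- apply(X, 2, pop_sd)
  if (divide_by == "variance") spread <- spread^2
  n_const <- sum(spread == 0)
  if (n_const > 0)
    message(sprintf("%d constant feature(s); scale set to 1", n_const))
  spread[spread == 0] <- 1
  out <- list(center = center, scale = spread, divide_by = divide_by)
  if (!is.null(y)) {
    out$y_center <- mean(y)
    ys <- pop_sd(y)
    if (divide_by == "variance") ys <- ys^2
    out$y_scale <- if (ys == 0) 1 else ys
  }
  structure(out, class = "scaler")
}

#' Apply a fitted standardizer
#'
#' @param scaler A [fit_standardizer()] object.
#' @param X Optional matrix to standardize (must match the fitted width).
#' @param y Optional target vector to standardize.
#' @return List with standardized `X` and/or `y`.
#' @export
apply_standardizer <- function(scaler, X = NULL, y = NULL) {
  stopifnot(inherits(scaler, "scaler"))
  out <- list()
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) != length(scaler$center))
      fail("matrix has %d columns but the scaler was fitted on %d",
           ncol(X), length(scaler$center))
    out$X <- sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
  }
  if (!is.null(y)) {
    if (is.null(scaler$y_center)) fail("scaler was fitted without a target")
    out$y <- (y - scaler$y_center) / scaler$y_scale
  }
  out
}

#' Invert a fitted standardizer (anti-normalization)
#'
#' @inheritParams apply_standardizer
#' @return List with back-transformed `X` and/or `y`.
#' @export
invert_standardizer <- function(scaler, X = NULL, y = NULL) {
  stopifnot(inherits(scaler, "scaler"))
  out <- list()
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) != length(scaler$center))
      fail("matrix has %d columns but the scaler was fitted on %d",
           ncol(X), length(scaler$center))
    out$X <- sweep(sweep(X, 2, scaler$scale, "*"), 2, scaler$center, "+")
  }
  if (!is.null(y)) {
    if (is.null(scaler$y_center)) fail("scaler was fitted without a target")
    out$y <- y * scaler$y_scale + scaler$y_center
  }
  out
}
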