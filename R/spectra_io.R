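# Spectral containers and plain-text I/O.
#
# Two dialects are supported: whitespace-delimited SVC-style ASCII for raw
# radiance records (wavelength, reference, target, percent), and CSV tables
# with metadata columns followed by one numeric wavelength column per channel.

#' Construct a single spectrum
#'
#' A spectrum couples a strictly increasing wavelength grid (nm) with one
#' value per wavelength. Reflectance values are dimensionless; values above
#' 1 are tolerated up to 1.5 (calibration overshoot near noisy bands) with a
#' warning, and rejected above 1.5. Radiance values are instrument units and
#' not range-checked.
#'
#' @param wavelengths Numeric vector, nm, strictly increasing.
#' @param values Numeric vector of the same length.
#' @param value_kind Either `"reflectance"` or `"radiance"`.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths, values, value_kind = c("reflectance", "radiance")) {
  value_kind <- match.arg(value_kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    fail("wavelengths (%d) and values (%d) differ in length",
         length(wavelengths), length(values))
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    fail("wavelengths must be strictly increasing")
  if (anyNA(wavelengths) || anyNA(values))
    fail("spectrum contains missing values")
  if (value_kind == "reflectance") {
    if (any(values < 0) || any(values > 1.5))
      fail("reflectance values outside [0, 1.5]: range [%g, %g]",
           min(values), max(values))
    if (any(values > 1))
      warning(sprintf("%d reflectance value(s) exceed 1.0 (calibration overshoot, retained)",
                      sum(values > 1)), call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, values = values,
                 value_kind = value_kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d channels, %.1f-%.1f nm, kind: %s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$value_kind))
  invisible(x)
}

meta_key <- function(meta) {
  paste(meta$genotype_id, meta$treatment, meta$stage, meta$replicate, sep = "/")
}

#' Construct a set of spectra on a shared wavelength grid
#'
#' @param grid Numeric vector, nm, strictly increasing; shared by all rows.
#' @param meta Data frame with columns `sample_id`, `genotype_id`,
#'   `treatment` (CK/DS), `stage`, `replicate`; the tuple
#'   (genotype_id, treatment, stage, replicate) must be unique.
#' @param values Numeric matrix, one row per sample, `length(grid)` columns.
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(grid, meta, values) {
  grid <- as.numeric(grid)
  values <- as.matrix(values)
  if (length(grid) > 1 && any(diff(grid) <= 0))
    fail("grid wavelengths must be strictly increasing")
  need <- c("sample_id", "genotype_id", "treatment", "stage", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    fail("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(meta) != nrow(values))
    fail("metadata has %d rows but values has %d", nrow(meta), nrow(values))
  if (ncol(values) != length(grid))
    fail("values has %d columns but the grid has %d wavelengths",
         ncol(values), length(grid))
  check_treatment(meta$treatment)
  check_stage(meta$stage)
  key <- meta_key(meta)
  if (anyDuplicated(key))
    fail("duplicate (genotype, treatment, stage, replicate) key(s): %s",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (anyDuplicated(meta$sample_id))
    fail("duplicate sample_id(s): %s",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  meta <- as.data.frame(meta)[, need]
  rownames(meta) <- NULL
  dimnames(values) <- NULL
  structure(list(grid = grid, meta = meta, values = values),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d channels (%.1f-%.1f nm)\n",
              nrow(x$values), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Number of samples in a spectra set
#' @param set A `spectra_set`.
#' @return Integer sample count.
#' @export
n_samples <- function(set) nrow(set$values)

#' Subset a spectra set by row index or metadata predicate
#'
#' @param set A `spectra_set`.
#' @param idx Integer or logical row index.
#' @return A `spectra_set` with the selected rows.
#' @export
subset_spectra <- function(set, idx) {
  spectra_set(set$grid, set$meta[idx, , drop = FALSE],
              set$values[idx, , drop = FALSE])
}

#' Read an SVC-style ASCII radiance file
#'
#' Expects whitespace-delimited rows of at least four numeric columns:
#' wavelength (nm), reference radiance, target radiance, and percent
#' (100 * target/reference). Leading banner lines and `#`-prefixed comments
#' are skipped; once numeric data begins, every row must parse with a
#' consistent column count.
#'
#' @param path Path to the file.
#' @return A list with elements `reference` and `target` (radiance
#'   [spectrum] objects) and `percent`, the fourth column converted to a
#'   fraction in `[0, 1]`-ish units.
#' @examples
#' f <- system.file("extdata", "synthetic_svc_leaf.txt", package = "fvfmspec")
#' rec <- read_svc_ascii(f)
#' head(calibrate_reflectance(rec$target$values, rec$reference$values, 0.99))
#' @export
read_svc_ascii <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  parse_row <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    suppressWarnings(as.numeric(tok))
  }
  is_blank_or_comment <- function(ln) {
    t <- trimws(ln)
    !nzchar(t) || startsWith(t, "#")
  }
  in_data <- FALSE
  rows <- list()
  for (i in seq_along(lines)) {
    if (is_blank_or_comment(lines[i])) next
    vals <- parse_row(lines[i])
    ok <- length(vals) >= 4 && !anyNA(vals)
    if (!in_data) {
      if (!ok) next  # header banner
      in_data <- TRUE
      ncol_data <- length(vals)
    } else if (!ok || length(vals) != ncol_data) {
      fail("malformed data row at line %d of %s", i, path)
    }
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows)) fail("no numeric data rows found in %s", path)
  m <- do.call(rbind, rows)
  if (any(diff(m[, 1]) <= 0))
    fail("wavelengths are not strictly increasing in %s", path)
  list(reference = spectrum(m[, 1], m[, 2], "radiance"),
       target = spectrum(m[, 1], m[, 3], "radiance"),
       percent = m[, 4] / 100)
}

#' Read a spectral table (CSV) into a spectra set
#'
#' The table must have the five metadata columns (`sample_id`,
#' `genotype_id`, `treatment`, `stage`, `replicate`) followed by one column
#' per wavelength, each with a numeric wavelength header in nm.
#'
#' @param path Path to the CSV file.
#' @return A [spectra_set].
#' @export
read_spectra_table <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype_id", "treatment", "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fail("spectral table is missing metadata column(s): %s",
         paste(miss, collapse = ", "))
  wl_names <- setdiff(names(df), need)
  grid <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(grid))
    fail("non-numeric wavelength header(s): %s",
         paste(wl_names[is.na(grid)], collapse = ", "))
  values <- as.matrix(df[, wl_names, drop = FALSE])
  if (!is.numeric(values)) fail("ragged or non-numeric spectral values")
  spectra_set(grid, df[, need], values)
}

#' Write a spectra set to a CSV spectral table
#'
#' The output is re-readable by [read_spectra_table()]; values are written
#' at full double precision (more than 6 significant digits).
#'
#' @param set A [spectra_set].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectra_table <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  df <- cbind(set$meta,
              as.data.frame(set$values) |>
                stats::setNames(format(set$grid, trim = TRUE, digits = 10)))
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) fail("cannot write spectral table to %s", path)
  invisible(path)
}

#' Assemble a design matrix from a spectra set and Fv/Fm targets
#'
#' Rows are ordered deterministically by `sample_id`, so shuffling the input
#' set does not change the result.
#'
#' @param set A [spectra_set].
#' @param targets Named numeric vector mapping `sample_id` to Fv/Fm.
#' @return An object of class `"design_matrix"`: list with `X`
#'   (n x n_wavelengths), `y` (length n), `meta` (n rows), `grid`.
#' @export
to_design_matrix <- function(set, targets) {
  stopifnot(inherits(set, "spectra_set"))
  missing_ids <- setdiff(set$meta$sample_id, names(targets))
  if (length(missing_ids))
    fail("missing Fv/Fm target for sample(s): %s",
         paste(missing_ids, collapse = ", "))
  ord <- order(set$meta$sample_id)
  meta <- set$meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  X <- set$values[ord, , drop = FALSE]
  y <- as.numeric(targets[meta$sample_id])
  if (anyNA(y)) fail("non-finite Fv/Fm target values")
  structure(list(X = X, y = y, meta = meta, grid = set$grid),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d samples x %d wavelengths\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}
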