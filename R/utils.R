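# Internal helpers shared across modules.

#' Stage levels used throughout the package
#'
#' The three phenological stages at which spectra and fluorescence are
#' recorded, in chronological order.
#' @export
STAGES <- c("flowering", "boll_setting", "boll_opening")

# Run `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Stop with a formatted message, no call in the condition.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_treatment <- function(x) {
  if (!all(x %in% c("CK", "DS")))
    fail("treatment must be 'CK' or 'DS'; got: %s",
         paste(unique(setdiff(x, c("CK", "DS"))), collapse = ", "))
  invisible(x)
}

check_stage <- function(x) {
  if (!all(x %in% STAGES))
    fail("stage must be one of %s; got: %s", paste(STAGES, collapse = ", "),
         paste(unique(setdiff(x, STAGES)), collapse = ", "))
  invisible(x)
}
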