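# Internal helpers shared across modules.

ks_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("katharoseq_error_", class), "katharoseq_error"), ...)
}

# Positive-control classes carry a known input (cells or genome copies).
POSITIVE_CLASSES <- c("extraction_positive", "pcr_positive")
NEGATIVE_CLASSES <- c("extraction_negative", "pcr_negative", "blank")
CONTROL_CLASSES <- c(POSITIVE_CLASSES, NEGATIVE_CLASSES, "sample")

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Lower-central median: for even counts take the lower of the two middle
# values, so thresholds derived from integer read depths stay integers and
# stay conservative.
median_lower <- function(x) {
  stopifnot(length(x) > 0)
  sort(x)[ceiling(length(x) / 2)]
}
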