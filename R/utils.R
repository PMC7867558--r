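#' @keywords internal
"_PACKAGE"

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
# All generators in the package route their randomness through this helper so
# that every output is a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive independent child seeds from a master seed (kept below 2^31 - 1).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Case-insensitive electrode label matching; returns indices into `labels`
# or stops naming the offending label.
match_labels <- function(wanted, labels, context = "electrode") {
  idx <- match(toupper(wanted), toupper(labels))
  if (anyNA(idx)) {
    bad <- wanted[is.na(idx)]
    stop(sprintf("unknown %s label(s): %s", context,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
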