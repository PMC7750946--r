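# Internal helpers shared across modules.

# Derive a child seed from a global seed by a fixed stage offset, so each
# simulation stage is independently reproducible. Kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

# Stage offsets are fixed constants: re-running one stage with the same
# global seed always sees the same stream.
.seed_offsets <- c(
  genotypes   = 101L,
  exposure    = 202L,
  codes       = 303L,
  relatedness = 404L,
  unrelated   = 505L,
  bootstrap   = 606L
)

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# Format an odds ratio with its 95% CI the way epidemiological tables do.
format_or <- function(or, lo, hi, digits = 2) {
  sprintf("%.*f (%.*f-%.*f)", digits, or, digits, lo, digits, hi)
}
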