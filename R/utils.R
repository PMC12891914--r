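# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Standard genetic code keyed by codon (64 entries, "*" = stop).
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# Synonymous family of an amino acid: all codons translating to it.
codon_family <- function(aa) {
  gc <- genetic_code()
  names(gc)[gc == aa]
}

# Split an in-frame sequence into codons. Length must be divisible by 3.
split_codons <- function(seq) {
  stopifnot(nchar(seq) %% 3 == 0)
  n <- nchar(seq) %/% 3
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# Translate an in-frame nucleotide string; stops become "*".
translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

# Deterministic per-stage child seeds fanned out from one master seed.
# Counter-based so each stage is individually reproducible; kept < 2^31.
child_seed <- function(seed, counter) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(counter)) %% 2147483647
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards so library code never disturbs user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
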