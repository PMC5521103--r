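DNA_BASES <- c("A", "C", "G", "T")

# integer encoding A=0 C=1 G=2 T=3 used by the C++ kernels
dna_int <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
}

int_dna <- function(x) {
  paste(DNA_BASES[x + 1L], collapse = "")
}

is_dna <- function(seq) {
  is.character(seq) && length(seq) == 1L && !is.na(seq) &&
    nchar(seq) > 0L && grepl("^[ACGT]+$", seq)
}

# Validate one sequence; returns the uppercased string or aborts naming the
# record and the 1-based position of the first offending character.
check_dna <- function(seq, id = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("'%s' must be a single character string.", id))
  }
  if (nchar(seq) == 0L) {
    abort(sprintf("Record '%s' has an empty sequence.", id))
  }
  seq <- toupper(seq)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    abort(sprintf(
      "Record '%s' contains invalid character '%s' at position %d (alphabet is A/C/G/T; ambiguity codes are rejected).",
      id, substr(seq, bad, bad), bad))
  }
  seq
}

# Run code with a private RNG stream so callers' .Random.seed is untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}
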