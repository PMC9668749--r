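# Internal helpers shared across modules.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) cpp_random_dna(as.numeric(n))

# Hamming distance between equal-length strings (raw-byte compare).
str_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_char_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  if (is.character(x)) return(x)
  stop("expected a character vector or DNAStringSet of sequences")
}

# NG50 against an assumed genome size G: the largest length L such that
# sequences of length >= L sum to at least G/2.
ng50 <- function(lengths, G) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(lengths)
  hit <- which(cum >= G / 2)
  if (length(hit) == 0L) return(structure(0, short = TRUE))
  structure(lengths[hit[1L]], short = FALSE)
}
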