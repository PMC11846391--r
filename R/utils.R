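# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so that seeded internals never disturb the
#' session RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept strictly below 2^31 so every derived
# seed is a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1000003) * 2039 + offset) %% 2147483629L + 1L
}

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a single sequence into a character vector of bases.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Classify substitution columns between two equal-length base vectors.
# Returns counts of matches, transitions (A<->G, C<->T) and transversions.
# Positions containing N (either side) are excluded from all counts.
classify_subst <- function(a, b) {
  keep <- a != "N" & b != "N"
  a <- a[keep]; b <- b[keep]
  same <- a == b
  pur_a <- a %in% PURINES
  pur_b <- b %in% PURINES
  ts <- !same & (pur_a == pur_b)
  list(sites = length(a), matches = sum(same),
       transitions = sum(ts), transversions = sum(!same & !ts))
}

# Random DNA string(s); base probabilities default to uniform.
random_dna <- function(n, len, prob = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

# All rotations of a string.
rotations <- function(s) {
  n <- nchar(s)
  if (n == 1L) return(s)
  d <- paste0(s, s)
  vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1))
}

is_dna <- function(x) grepl("^[ACGTN]*$", x)

# Phred+33 character string <-> integer vector conversions.
qual_to_int <- function(q) as.integer(charToRaw(q)) - 33L
int_to_qual <- function(x) rawToChar(as.raw(x + 33L))
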