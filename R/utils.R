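# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is restored afterwards, so generators are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Uniform integer in [lo, hi]; immune to sample()'s scalar expansion.
rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

random_protein <- function(n, freqs = NULL) {
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = freqs), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Alphabetically-first codon per amino acid under the standard code; used for
# deterministic back-translation of reference proteins when planting genes.
backtranslate_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split_codons <- split(names(gc), unname(gc))
  vapply(split_codons, function(cs) sort(cs)[1], character(1))
}

backtranslate <- function(protein) {
  codons <- backtranslate_codons()
  aa <- seq_chars(protein)
  bad <- setdiff(aa, names(codons))
  if (length(bad) > 0) {
    stop("cannot back-translate residue(s): ", paste(unique(bad), collapse = ", "))
  }
  paste(codons[aa], collapse = "")
}

interval_str <- function(start, end) sprintf("[%d,%d)", start, end)

`%||%` <- function(a, b) if (is.null(a)) b else a
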