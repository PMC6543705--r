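#' Nucleotide scoring scheme with Karlin-Altschul statistics
#'
#' Defaults approximate blastn-style +1/-2 scoring with affine gaps; `lambda`
#' and `K` parameterise the E-value `E = K * m * n * exp(-lambda * S)` used to
#' weight similarity edges between circles. A gap of length L costs
#' `|gap_open| + |gap_extend| * L`.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening score (negative).
#' @param gap_extend Gap extension score per base (negative).
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -2, lambda = 1.28, K = 0.46) {
  stopifnot(match > 0, mismatch < 0, lambda > 0, K > 0)
  structure(list(type = "dna", match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Protein scoring scheme (BLOSUM62, affine gaps)
#'
#' BLOSUM62 substitution scores with blastp-style gap costs and the standard
#' gapped Karlin-Altschul parameters for that matrix.
#'
#' @param gap_open,gap_extend Affine gap scores (negative).
#' @param lambda,K Karlin-Altschul parameters.
#' @return A list of class `scoring_scheme`.
#' @export
protein_scheme <- function(gap_open = -11, gap_extend = -1,
                           lambda = 0.267, K = 0.041) {
  structure(list(type = "protein", matrix = "BLOSUM62",
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

substitution_matrix <- function(scheme) {
  if (scheme$type == "protein") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    return(e$BLOSUM62)
  }
  letters <- c(DNA_BASES, "N")
  m <- matrix(scheme$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scheme$match
  # N counts as a mismatch everywhere, including against itself
  m["N", ] <- scheme$mismatch
  m[, "N"] <- scheme$mismatch
  m
}

ka_evalue <- function(score, m, n, scheme) {
  scheme$K * m * n * exp(-scheme$lambda * score)
}

# Identity over aligned columns, gaps included in the denominator.
alignment_identity <- function(pattern_aln, subject_aln) {
  p <- seq_chars(pattern_aln)
  s <- seq_chars(subject_aln)
  100 * sum(p == s & p != "-") / length(p)
}

# Best local alignment of a pattern/subject pair in one orientation.
# Returns a one-row tibble of hit statistics (0-based half-open spans).
align_local <- function(a, b, scheme, query_id = "query", subject_id = "subject",
                        frame = 0L) {
  sub_mat <- substitution_matrix(scheme)
  cls <- if (scheme$type == "protein") Biostrings::AAString else Biostrings::DNAString
  pa <- Biostrings::pairwiseAlignment(
    cls(a), cls(b), type = "local", substitutionMatrix = sub_mat,
    gapOpening = abs(scheme$gap_open), gapExtension = abs(scheme$gap_extend))
  s <- Biostrings::score(pa)
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  tibble(
    query_id = query_id, subject_id = subject_id,
    score = s,
    evalue = ka_evalue(s, nchar(a), nchar(b), scheme),
    identity = alignment_identity(as.character(Biostrings::alignedPattern(pa)),
                                  as.character(Biostrings::alignedSubject(pa))),
    query_start = Biostrings::start(pat) - 1L,
    query_end = Biostrings::end(pat),
    subject_start = Biostrings::start(sub) - 1L,
    subject_end = Biostrings::end(sub),
    frame = as.integer(frame)
  )
}

# Vectorised local-alignment scores of many patterns against one subject.
align_scores_vs_subject <- function(patterns, subject, scheme) {
  sub_mat <- substitution_matrix(scheme)
  setcls <- if (scheme$type == "protein") Biostrings::AAStringSet else Biostrings::DNAStringSet
  strcls <- if (scheme$type == "protein") Biostrings::AAString else Biostrings::DNAString
  Biostrings::pairwiseAlignment(
    setcls(patterns), strcls(subject), type = "local",
    substitutionMatrix = sub_mat,
    gapOpening = abs(scheme$gap_open), gapExtension = abs(scheme$gap_extend),
    scoreOnly = TRUE)
}

# Global (Needleman-Wunsch) identity between two proteins, used by the
# synthetic proteome generator and its oracle tests.
global_identity <- function(a, b, scheme = protein_scheme()) {
  sub_mat <- substitution_matrix(scheme)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = sub_mat,
    gapOpening = abs(scheme$gap_open), gapExtension = abs(scheme$gap_extend))
  alignment_identity(as.character(Biostrings::alignedPattern(pa)),
                     as.character(Biostrings::alignedSubject(pa)))
}
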