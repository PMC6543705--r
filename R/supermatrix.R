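#' Select the best candidate sequence per species for an orthologous group
#'
#' Each candidate is scored as the sum of its protein local-alignment scores
#' against all existing members of the group; the highest-scoring candidate is
#' kept. Ties are broken by longer sequence, then by id.
#'
#' @param candidates Tibble (`id`, `seq`) of candidate sequences for one
#'   species.
#' @param members Character vector of existing group member sequences
#'   (gaps are stripped before alignment).
#' @param scheme A [protein_scheme].
#' @return The selected row of `candidates` (one-row tibble) with a
#'   `group_score` column.
#' @export
best_per_species <- function(candidates, members, scheme = protein_scheme()) {
  stopifnot(nrow(candidates) >= 1)
  members <- gsub("[-X]", "", toupper(members))
  members <- members[nchar(members) > 0]
  scores <- vapply(seq_len(nrow(candidates)), function(i) {
    sum(vapply(members, function(m) {
      align_scores_vs_subject(candidates$seq[i], m, scheme)
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-scores, -nchar(candidates$seq), candidates$id)
  out <- candidates[ord[1], , drop = FALSE]
  out$group_score <- scores[ord[1]]
  as_tibble(out)
}

#' Merge closely related species into chimeric OTUs
#'
#' Within each partition, among the member species of a merge row that are
#' present, the sequence with the most non-missing residues (not `-` or `X`)
#' represents the chimera; the other members are dropped and the chimera
#' label replaces the member label. Species absent from every partition yield
#' a chimera absent from the output. Species not listed in any merge row pass
#' through unchanged.
#'
#' @param partitions List of [alignment]s.
#' @param merge_table Tibble with `chimera` (character) and `members` (list of
#'   character vectors), e.g. from [read_merge_table].
#' @return List of merged [alignment]s.
#' @export
merge_chimeric <- function(partitions, merge_table) {
  merge_table <- validate_merge_table(merge_table)
  lapply(partitions, function(aln) {
    taxa <- aln$taxon
    keep <- rep(TRUE, nrow(aln))
    labels <- taxa
    for (i in seq_len(nrow(merge_table))) {
      present <- which(taxa %in% merge_table$members[[i]])
      if (length(present) == 0) next
      res <- nchar(gsub("[-X]", "", aln$seq[present]))
      best <- present[order(-res, taxa[present])[1]]
      drop <- setdiff(present, best)
      keep[drop] <- FALSE
      labels[best] <- merge_table$chimera[i]
    }
    alignment(labels[keep], aln$seq[keep], name = attr(aln, "name", exact = TRUE))
  })
}

#' Remove poorly represented species from all partitions
#' @param partitions List of [alignment]s.
#' @param species Character vector of taxon labels to drop.
#' @return List of [alignment]s.
#' @export
remove_species <- function(partitions, species) {
  lapply(partitions, function(aln) {
    keep <- !aln$taxon %in% species
    alignment(aln$taxon[keep], aln$seq[keep], name = attr(aln, "name", exact = TRUE))
  })
}

#' Trim alignment columns by gap fraction
#'
#' A column is retained iff its gap fraction is at most `gap_threshold`
#' (gap is `-` only; `X` counts as a residue here). The boundary is
#' inclusive: a column with exactly half gaps is retained at the default 0.5.
#'
#' @param aln An [alignment].
#' @param gap_threshold Maximum tolerated gap fraction (default 0.5).
#' @return Trimmed [alignment].
#' @export
trim_columns <- function(aln, gap_threshold = 0.5) {
  m <- aln_matrix(aln)
  if (ncol(m) == 0) return(aln)
  gap_frac <- colMeans(m == "-")
  aln_from_matrix(m[, gap_frac <= gap_threshold, drop = FALSE],
                  name = attr(aln, "name", exact = TRUE))
}

#' Remove invariant columns
#'
#' Drops columns with at most one distinct non-missing residue (`-` and `X`
#' are missing).
#'
#' @param aln An [alignment].
#' @return Filtered [alignment].
#' @export
remove_invariant <- function(aln) {
  m <- aln_matrix(aln)
  if (ncol(m) == 0) return(aln)
  variable <- apply(m, 2, function(col) {
    length(unique(col[!col %in% c("-", "X")])) > 1
  })
  aln_from_matrix(m[, variable, drop = FALSE], name = attr(aln, "name", exact = TRUE))
}

#' Concatenate partitions into a supermatrix
#'
#' Takes the union of taxa (in order of first appearance); blocks for taxa
#' absent from a partition are filled with `-`. The missing-data fraction
#' counts both `-` and `X` over the full taxa-by-positions matrix. Partition
#' offsets are 0-based half-open and contiguous.
#'
#' @param partitions List of [alignment]s.
#' @return Object of class `supermatrix`: `alignment` (the concatenated
#'   [alignment]), `total_positions`, `missing_fraction`, `offsets` (tibble
#'   `partition`, `start`, `end`), `n_taxa`.
#' @export
concatenate_partitions <- function(partitions) {
  stopifnot(length(partitions) >= 1)
  taxa <- unique(unlist(lapply(partitions, function(a) a$taxon)))
  widths <- vapply(partitions, function(a) if (nrow(a)) nchar(a$seq[1]) else 0L,
                   numeric(1))
  total <- sum(widths)
  big <- matrix("-", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  at <- 0L
  names_p <- vapply(seq_along(partitions), function(i) {
    attr(partitions[[i]], "name", exact = TRUE) %||% sprintf("partition_%03d", i)
  }, character(1))
  for (i in seq_along(partitions)) {
    a <- partitions[[i]]
    if (widths[i] > 0 && nrow(a) > 0) {
      big[a$taxon, (at + 1):(at + widths[i])] <- aln_matrix(a)
    }
    at <- at + widths[i]
  }
  offsets <- tibble(partition = names_p,
                    start = cumsum(c(0, widths[-length(widths)])),
                    end = cumsum(widths))
  missing_fraction <- mean(big %in% c("-", "X"))
  structure(list(alignment = aln_from_matrix(big, name = "supermatrix"),
                 total_positions = as.integer(total),
                 missing_fraction = missing_fraction,
                 offsets = offsets, n_taxa = length(taxa)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", x$n_taxa, "taxa x", x$total_positions, "positions;",
      sprintf("%.1f%% missing data", 100 * x$missing_fraction), "\n")
  cat("  partitions:", nrow(x$offsets), "\n")
  invisible(x)
}

#' Relative composition frequency variability (RCFV) of a partition
#'
#' Per-taxon residue frequencies `f[t, s]` are computed over non-missing
#' residues (`-` and `X` are missing); with `mu[s]` the mean frequency across
#' taxa, `RCFV = sum_s sum_t |f[t, s] - mu[s]| / n_taxa`. Taxa with no
#' residues at all are flagged and excluded from the average.
#'
#' @param aln An [alignment].
#' @return Object of class `composition_profile`: `f` (taxon x state matrix),
#'   `mu`, `rcfv`, `all_missing` (taxon labels excluded).
#' @export
rcfv <- function(aln) {
  m <- aln_matrix(aln)
  states <- AA_ALPHABET
  counts <- t(apply(m, 1, function(row) {
    r <- row[!row %in% c("-", "X")]
    tabulate(factor(r, levels = states), nbins = length(states))
  }))
  colnames(counts) <- states
  tot <- rowSums(counts)
  all_missing <- rownames(m)[tot == 0]
  f <- counts[tot > 0, , drop = FALSE] / tot[tot > 0]
  mu <- colMeans(f)
  val <- sum(abs(sweep(f, 2, mu))) / nrow(f)
  structure(list(f = f, mu = mu, rcfv = val, all_missing = all_missing),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("RCFV = %.4f over %d taxa", x$rcfv, nrow(x$f)))
  if (length(x$all_missing)) cat(" (", length(x$all_missing), "all-missing taxa excluded)")
  cat("\n")
  invisible(x)
}

#' Filter partitions by compositional heterogeneity
#'
#' Discards partitions whose RCFV strictly exceeds `rcfv_max`.
#'
#' @param partitions List of [alignment]s.
#' @param rcfv_max RCFV cutoff (default 0.115).
#' @return List with `kept`, `discarded` (lists of alignments) and `report`
#'   (tibble `partition`, `rcfv`, `kept`).
#' @export
rcfv_filter <- function(partitions, rcfv_max = 0.115) {
  vals <- vapply(partitions, function(a) rcfv(a)$rcfv, numeric(1))
  nm <- vapply(seq_along(partitions), function(i) {
    attr(partitions[[i]], "name", exact = TRUE) %||% sprintf("partition_%03d", i)
  }, character(1))
  keep <- vals <= rcfv_max
  list(kept = partitions[keep], discarded = partitions[!keep],
       report = tibble(partition = nm, rcfv = vals, kept = keep))
}

DAYHOFF6 <- c(
  A = "1", G = "1", P = "1", S = "1", T = "1",
  D = "2", E = "2", N = "2", Q = "2",
  H = "3", K = "3", R = "3",
  F = "4", W = "4", Y = "4",
  I = "5", L = "5", M = "5", V = "5",
  C = "6"
)

#' Dayhoff six-group recoding
#'
#' Collapses the 20 amino acids into the six Dayhoff exchange groups
#' (AGPST, DENQ, HKR, FWY, ILMV, C), written as symbols 1-6. Gaps (`-`) and
#' `X` are preserved.
#'
#' @param x An [alignment], a character matrix, or a character vector of
#'   sequences.
#' @return Same shape as the input, recoded.
#' @export
dayhoff_recode <- function(x) {
  recode_string <- function(s) {
    chars <- seq_chars(s)
    known <- chars %in% names(DAYHOFF6)
    chars[known] <- DAYHOFF6[chars[known]]
    paste(chars, collapse = "")
  }
  if (inherits(x, "circlemat_aln")) {
    return(alignment(x$taxon, vapply(x$seq, recode_string, character(1)),
                     name = attr(x, "name", exact = TRUE)))
  }
  if (is.matrix(x)) {
    out <- x
    known <- x %in% names(DAYHOFF6)
    out[known] <- DAYHOFF6[x[known]]
    return(out)
  }
  vapply(x, recode_string, character(1), USE.NAMES = FALSE)
}
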