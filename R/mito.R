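#' Six-frame translation of a circular sequence
#'
#' Translation is performed on the doubled sequence (the circle concatenated
#' with itself) so that every open reading frame, including those spanning the
#' origin, appears contiguously in one of the frame streams. Reverse-strand
#' frames translate the doubled reverse complement. Stop codons are retained
#' as `*` in the peptide streams; codons containing `N` translate to `X`.
#' Because of the doubling, a gene wholly inside the circle body appears twice
#' across the streams; downstream users work modulo the circle length.
#'
#' @param circle_seq DNA sequence of the circle body (terminal repeat
#'   removed).
#' @return Tibble with columns `frame` (1..3), `strand` (`+`/`-`), `peptide`.
#'   The codon for residue `j` of frame `f` starts at circle position
#'   `(f - 1 + 3 (j - 1)) mod n` (0-based) on the given strand.
#' @export
circular_sixframe <- function(circle_seq) {
  n <- nchar(circle_seq)
  translate_frames <- function(s, strand) {
    ext <- paste0(s, s)
    purrr::map_dfr(0:2, function(f) {
      sub <- substr(ext, 1 + f, nchar(ext))
      sub <- substr(sub, 1, (nchar(sub) %/% 3) * 3)
      pep <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X"))
      tibble(frame = f + 1L, strand = strand, peptide = pep)
    })
  }
  bind_rows(translate_frames(circle_seq, "+"),
            translate_frames(revcomp(circle_seq), "-"))
}

# All protein-level hits of one circle's frame streams against a reference
# set, at a given E-value threshold.
frame_hits <- function(circle_seq, refs, scheme, evalue_threshold) {
  frames <- circular_sixframe(circle_seq)
  hits <- list()
  for (i in seq_len(nrow(frames))) {
    pep <- frames$peptide[i]
    if (nchar(pep) < 5) next
    for (r in seq_along(refs)) {
      h <- align_local(pep, refs[[r]], scheme,
                       query_id = paste0(frames$strand[i], frames$frame[i]),
                       subject_id = names(refs)[r],
                       frame = frames$frame[i])
      h$strand <- frames$strand[i]
      h$peptide <- pep
      if (h$evalue <= evalue_threshold) hits[[length(hits) + 1]] <- h
    }
  }
  bind_rows(hits)
}

#' Annotate mini-circles by similarity to reference mitochondrial proteins
#'
#' For each circle, all six circular frame translations are locally aligned
#' (BLOSUM62, affine gaps) against every reference protein; the circle is
#' assigned the best-scoring reference with E-value at most
#' `evalue_threshold`. Pseudogene lesions are flagged: `in_frame_stop` when
#' the aligned circle region contains a stop codon, and `frameshift` when two
#' hits to the assigned reference occupy different frames of the same strand
#' with essentially non-overlapping reference spans. The coding span is
#' reported in 0-based circle coordinates and may wrap past the origin
#' (`coding_end` > circle length denotes wrap-around); the remainder of the
#' circle is the non-coding region.
#'
#' @param circles Tibble with `id` and a sequence column (`trimmed_seq`
#'   preferred).
#' @param refs Named character vector of reference protein sequences.
#' @param evalue_threshold E-value threshold (default 0.008).
#' @param scheme A [protein_scheme].
#' @return Tibble with one row per circle: `circle_id`, `gene` (`NA` when
#'   unassigned), `score`, `evalue`, `identity`, `orientation`, `frame`,
#'   `coding_start`, `coding_end`, `in_frame_stop`, `frameshift`.
#' @export
annotate_circles <- function(circles, refs, evalue_threshold = 0.008,
                             scheme = protein_scheme()) {
  seq_col <- if ("trimmed_seq" %in% names(circles)) "trimmed_seq" else "seq"
  refs <- unlist(refs)
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  purrr::map_dfr(seq_len(nrow(circles)), function(i) {
    s <- circles[[seq_col]][i]
    n <- nchar(s)
    hits <- frame_hits(s, refs, scheme, evalue_threshold)
    if (nrow(hits) == 0) {
      return(tibble(circle_id = circles$id[i], gene = NA_character_,
                    score = NA_real_, evalue = NA_real_, identity = NA_real_,
                    orientation = NA_character_, frame = NA_integer_,
                    coding_start = NA_integer_, coding_end = NA_integer_,
                    in_frame_stop = FALSE, frameshift = FALSE))
    }
    hits <- arrange(hits, dplyr::desc(.data$score), .data$subject_id)
    best <- hits[1, ]
    gene <- best$subject_id
    # stop codon inside the aligned span of the chosen frame stream
    span_pep <- substr(best$peptide, best$query_start + 1, best$query_end)
    has_stop <- grepl("*", span_pep, fixed = TRUE)
    # frameshift: two same-strand hits to the assigned gene in different
    # frames whose reference spans barely overlap
    same_gene <- filter(hits, .data$subject_id == gene,
                        .data$strand == best$strand)
    fs <- FALSE
    if (nrow(same_gene) > 1) {
      for (a in 1:(nrow(same_gene) - 1)) for (b in (a + 1):nrow(same_gene)) {
        if (same_gene$frame[a] == same_gene$frame[b]) next
        ov <- min(same_gene$subject_end[a], same_gene$subject_end[b]) -
          max(same_gene$subject_start[a], same_gene$subject_start[b])
        shorter <- min(same_gene$subject_end[a] - same_gene$subject_start[a],
                       same_gene$subject_end[b] - same_gene$subject_start[b])
        if (ov < 0.5 * shorter) fs <- TRUE
      }
    }
    start_nt <- (best$frame - 1L) + 3L * best$query_start
    end_nt <- (best$frame - 1L) + 3L * best$query_end
    if (best$strand == "-") {
      # map back from the reverse-complement coordinate system
      tmp <- n - end_nt
      end_nt <- n - start_nt
      start_nt <- tmp
      if (start_nt < 0) { start_nt <- start_nt + n; end_nt <- end_nt + n }
    }
    start_mod <- start_nt %% n
    tibble(circle_id = circles$id[i], gene = gene, score = best$score,
           evalue = best$evalue, identity = best$identity,
           orientation = best$strand, frame = best$frame,
           coding_start = as.integer(start_mod),
           coding_end = as.integer(start_mod + (end_nt - start_nt)),
           in_frame_stop = has_stop, frameshift = fs)
  })
}

# Map one read onto the indexed circles by exact k-mer seeding with ungapped
# extension; returns the circle index or NA.
map_read <- function(read, index, bodies, doubled, seed_k, min_identity) {
  for (r in c(read, revcomp(read))) {
    L <- nchar(r)
    if (L < seed_k) next
    seed_starts <- unique(c(1L, (L - seed_k + 1L) %/% 2L + 1L, L - seed_k + 1L))
    for (s in seed_starts) {
      kmer <- substr(r, s, s + seed_k - 1L)
      locs <- index[[kmer]]
      if (is.null(locs)) next
      for (li in seq_len(nrow(locs))) {
        ci <- locs$circle[li]
        start <- locs$pos[li] - (s - 1L)
        if (start < 1L) start <- start + nchar(bodies[ci])
        ref <- substr(doubled[ci], start, start + L - 1L)
        if (nchar(ref) < L) next
        idn <- mean(seq_chars(ref) == seq_chars(r))
        if (idn >= min_identity) return(ci)
      }
    }
  }
  NA_integer_
}

#' Paired-read test for an unprocessed precursor molecule
#'
#' Maps both mates of each pair onto the circles (exact k-mer seeding on the
#' doubled circle sequences, ungapped extension at >= `min_identity` over the
#' read, both strands). Pairs with at least one mapped mate are categorised:
#' the partner is low complexity (DUST fraction > 0.5, checked before
#' mapping), maps to the same circle, or does not (`mate_elsewhere`). If more
#' than `threshold` of the pairs fall in `mate_elsewhere`, the data are
#' consistent with the circles being cut from a larger precursor molecule.
#'
#' @param pairs Tibble with columns `mate1`, `mate2` (e.g. from
#'   [gen_read_pairs]).
#' @param circles Tibble with `id` and a sequence column (`trimmed_seq`
#'   preferred); sequences are treated as circle bodies.
#' @param seed_k Seed k-mer length (default 31).
#' @param min_identity Ungapped identity required over the full read
#'   (default 0.9).
#' @param dust_threshold DUST fraction above which a mate is low complexity.
#' @param threshold `mate_elsewhere` fraction above which precursor evidence
#'   is declared (default 0.01).
#' @return Object of class `pair_map_report` with counts per category,
#'   `n_unanchored` (pairs where neither mate maps) and the
#'   `precursor_evidence` flag.
#' @export
precursor_pair_test <- function(pairs, circles, seed_k = 31,
                                min_identity = 0.9, dust_threshold = 0.5,
                                threshold = 0.01) {
  seq_col <- if ("trimmed_seq" %in% names(circles)) "trimmed_seq" else "seq"
  bodies <- circles[[seq_col]]
  doubled <- paste0(bodies, bodies)
  # k-mer index over the doubled sequences (positions within the first copy)
  idx_tbl <- purrr::map_dfr(seq_along(bodies), function(ci) {
    n <- nchar(bodies[ci])
    starts <- seq_len(n)
    tibble(kmer = substring(doubled[ci], starts, starts + seed_k - 1L),
           circle = ci, pos = starts)
  })
  index <- split(idx_tbl[c("circle", "pos")], idx_tbl$kmer)

  n_pairs_in <- nrow(pairs)
  both_same <- 0L; low_comp <- 0L; elsewhere <- 0L; unanchored <- 0L
  for (i in seq_len(n_pairs_in)) {
    m1 <- pairs$mate1[i]; m2 <- pairs$mate2[i]
    c1 <- map_read(m1, index, bodies, doubled, seed_k, min_identity)
    anchor <- c1; partner <- m2
    if (is.na(anchor)) {
      c2 <- map_read(m2, index, bodies, doubled, seed_k, min_identity)
      anchor <- c2; partner <- m1
    }
    if (is.na(anchor)) { unanchored <- unanchored + 1L; next }
    if (dust_fraction(partner) > dust_threshold) {
      low_comp <- low_comp + 1L
    } else {
      cp <- map_read(partner, index, bodies, doubled, seed_k, min_identity)
      if (!is.na(cp) && cp == anchor) both_same <- both_same + 1L
      else elsewhere <- elsewhere + 1L
    }
  }
  n_anchored <- both_same + low_comp + elsewhere
  structure(list(n_pairs = n_anchored,
                 both_same_circle = both_same,
                 mate_low_complexity = low_comp,
                 mate_elsewhere = elsewhere,
                 n_unanchored = unanchored,
                 threshold = threshold,
                 precursor_evidence = n_anchored > 0 &&
                   elsewhere / n_anchored > threshold),
            class = "pair_map_report")
}

#' @export
print.pair_map_report <- function(x, ...) {
  cat("Paired-read precursor test\n")
  cat("  anchored pairs:", x$n_pairs,
      "(", x$n_unanchored, "pairs with no mapped mate )\n")
  cat("  both mates on one circle:", x$both_same_circle, "\n")
  cat("  partner low complexity:  ", x$mate_low_complexity, "\n")
  cat("  partner elsewhere:       ", x$mate_elsewhere, "\n")
  cat("  precursor evidence:", x$precursor_evidence, "\n")
  invisible(x)
}
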