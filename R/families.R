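#' Best local nucleotide alignment between two circles
#'
#' Optimal affine-gap local alignment (both strands searched, best kept) with
#' a Karlin-Altschul E-value `E = K * m * n * exp(-lambda * S)`.
#'
#' @param a,b DNA sequences (character scalars).
#' @param scheme A [scoring_scheme].
#' @param query_id,subject_id Labels for the hit record.
#' @return One-row tibble (`query_id`, `subject_id`, `score`, `evalue`,
#'   `identity`, 0-based half-open spans, `strand`).
#' @export
local_align_nt <- function(a, b, scheme = scoring_scheme(),
                           query_id = "query", subject_id = "subject") {
  fwd <- align_local(a, b, scheme, query_id, subject_id)
  rev <- align_local(revcomp(a), b, scheme, query_id, subject_id)
  best <- if (rev$score > fwd$score) mutate(rev, strand = "-") else
    mutate(fwd, strand = "+")
  select(best, -"frame")
}

#' Cluster long circles into families by pairwise similarity
#'
#' Builds an undirected graph on the circles with an edge wherever the best
#' local-alignment E-value (either strand, either direction; self-hits
#' excluded) is at most `evalue_threshold`; families are the connected
#' components. Mirrors an all-against-all blastn graph in which edges above
#' the E-value cutoff are deleted.
#'
#' @param circles Tibble with `id` and a sequence column (`trimmed_seq`
#'   preferred).
#' @param evalue_threshold E-value cutoff for an edge (default `1e-10`).
#' @param scheme A [scoring_scheme].
#' @return Object of class `circle_families`: `membership` (tibble `id`,
#'   `family`, `family_size`), `size_histogram` (tibble `family_size`, `n`),
#'   `neighbor_fraction` (share of circles with at least one neighbor) and
#'   `n_families`.
#' @export
build_families <- function(circles, evalue_threshold = 1e-10,
                           scheme = scoring_scheme()) {
  seq_col <- if ("trimmed_seq" %in% names(circles)) "trimmed_seq" else "seq"
  seqs <- circles[[seq_col]]
  ids <- circles$id
  n <- length(seqs)
  has_edge <- matrix(FALSE, n, n)
  if (n > 1) {
    rc <- revcomp(seqs)
    for (j in 2:n) {
      pats <- seqs[1:(j - 1)]
      s_fwd <- align_scores_vs_subject(pats, seqs[j], scheme)
      s_rev <- align_scores_vs_subject(rc[1:(j - 1)], seqs[j], scheme)
      s <- pmax(s_fwd, s_rev)
      ev <- ka_evalue(s, nchar(pats), nchar(seqs[j]), scheme)
      hit <- ev <= evalue_threshold
      has_edge[1:(j - 1), j] <- hit
      has_edge[j, 1:(j - 1)] <- hit
    }
  }
  g <- igraph::graph_from_adjacency_matrix(has_edge, mode = "undirected")
  comp <- igraph::components(g)
  membership <- tibble(id = ids,
                       family = as.integer(comp$membership)) |>
    group_by(.data$family) |>
    mutate(family_size = dplyr::n()) |>
    ungroup()
  size_hist <- membership |>
    dplyr::distinct(.data$family, .data$family_size) |>
    dplyr::count(.data$family_size, name = "n") |>
    arrange(.data$family_size)
  neighbor_fraction <- if (n == 0) NA_real_ else mean(rowSums(has_edge) > 0)
  structure(list(membership = membership, size_histogram = size_hist,
                 neighbor_fraction = neighbor_fraction,
                 n_families = comp$no),
            class = "circle_families")
}

#' @export
print.circle_families <- function(x, ...) {
  cat("Circle families:", x$n_families, "components over",
      nrow(x$membership), "circles\n")
  cat(sprintf("  circles with >= 1 neighbor: %.1f%%\n",
              100 * x$neighbor_fraction))
  print(x$size_histogram)
  invisible(x)
}
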