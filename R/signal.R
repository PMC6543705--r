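#' Define ingroup/outgroup taxon sets
#'
#' @param G1 Ingroup taxon labels.
#' @param G2 Outgroup taxon labels.
#' @return List of class `group_assignment`.
#' @export
group_assignment <- function(G1, G2) {
  stopifnot(length(G1) > 0, length(G2) > 0,
            length(intersect(G1, G2)) == 0)
  structure(list(G1 = G1, G2 = G2), class = "group_assignment")
}

# q statistic for one column (character vector named by taxon).
q_column <- function(column, g1_idx, g2_idx, signed = TRUE) {
  c1 <- column[g1_idx]; c2 <- column[g2_idx]
  miss1 <- c1 %in% c("-", "X"); miss2 <- c2 %in% c("-", "X")
  # "no more than a half" with integer arithmetic
  if (2L * sum(miss1) > length(c1) || 2L * sum(miss2) > length(c2)) {
    return(list(considered = FALSE, q = NA_real_, a = NA_character_))
  }
  r1 <- c1[!miss1]; r2 <- c2[!miss2]
  if (length(r1) == 0 || length(r2) == 0) {
    return(list(considered = FALSE, q = NA_real_, a = NA_character_))
  }
  f1 <- tabulate(factor(r1, levels = AA_ALPHABET), nbins = 20) / length(r1)
  f2 <- tabulate(factor(r2, levels = AA_ALPHABET), nbins = 20) / length(r2)
  d <- f1 - f2
  if (!signed) d <- abs(d)
  q <- max(d)
  a <- AA_ALPHABET[which(d == q)][1]  # ties to alphabetical first
  list(considered = TRUE, q = q, a = a)
}

#' Per-position synapomorphy statistic q(i)
#'
#' For each alignment column with no more than half missing data (`-` or `X`)
#' in each of the two groups, residue frequencies are computed within the
#' ingroup and the outgroup over non-missing residues, and
#' `q = max_a (f_G1(a) - f_G2(a))` -- the ingroup-oriented signed maximum over
#' the 20 amino acids -- with `a` the maximising residue (ties to the
#' alphabetically first). `q` is 1 exactly when the ingroup is monomorphic
#' for a residue the outgroup lacks. An absolute-difference variant is
#' available via `signed = FALSE`.
#'
#' @param aln An [alignment].
#' @param groups A [group_assignment]; both groups must be subsets of the
#'   alignment's taxa.
#' @param signed Use the signed ingroup-minus-outgroup difference (default)
#'   or its absolute value.
#' @return Tibble with one row per column: `column` (1-based), `considered`,
#'   `q`, `a`.
#' @export
compute_q <- function(aln, groups, signed = TRUE) {
  stopifnot(inherits(groups, "group_assignment"))
  m <- aln_matrix(aln)
  missing_taxa <- setdiff(c(groups$G1, groups$G2), rownames(m))
  if (length(missing_taxa)) {
    stop("group taxa not in alignment: ", paste(missing_taxa, collapse = ", "))
  }
  g1 <- match(groups$G1, rownames(m))
  g2 <- match(groups$G2, rownames(m))
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    r <- q_column(m[, j], g1, g2, signed = signed)
    tibble(column = j, considered = r$considered, q = r$q, a = r$a)
  })
}

#' Select partitions carrying group-specific signal
#'
#' A column is flagged when its `q` strictly exceeds `q_cut`; a partition is
#' selected when its flagged fraction (flagged columns / considered columns)
#' is at least `min_fraction`.
#'
#' @param partitions List of [alignment]s.
#' @param groups A [group_assignment].
#' @param q_cut Flagging threshold on q (default 0.5, strict).
#' @param min_fraction Selection threshold on the flagged fraction (default
#'   0.03, inclusive).
#' @param signed Passed to [compute_q].
#' @return Object of class `q_selection`: per-partition tibble (`partition`,
#'   `n_considered`, `n_flagged`, `flagged_fraction`, `selected`) plus totals
#'   (`n_selected`, `selected_positions` = summed considered positions of the
#'   selected partitions).
#' @export
select_partitions <- function(partitions, groups, q_cut = 0.5,
                              min_fraction = 0.03, signed = TRUE) {
  rows <- purrr::map_dfr(seq_along(partitions), function(i) {
    aln <- partitions[[i]]
    qs <- compute_q(aln, groups, signed = signed)
    n_cons <- sum(qs$considered)
    n_flag <- sum(qs$q > q_cut, na.rm = TRUE)
    frac <- if (n_cons > 0) n_flag / n_cons else 0
    tibble(partition = attr(aln, "name", exact = TRUE) %||% sprintf("partition_%03d", i),
           n_considered = n_cons, n_flagged = n_flag,
           flagged_fraction = frac,
           selected = n_cons > 0 & frac >= min_fraction)
  })
  structure(list(report = rows,
                 n_selected = sum(rows$selected),
                 selected_positions = sum(rows$n_considered[rows$selected]),
                 q_cut = q_cut, min_fraction = min_fraction),
            class = "q_selection")
}

#' @export
print.q_selection <- function(x, ...) {
  cat("Signal-based partition selection (q >", x$q_cut,
      ", flagged fraction >=", x$min_fraction, ")\n")
  cat("  selected:", x$n_selected, "of", nrow(x$report),
      "partitions;", x$selected_positions, "considered positions in total\n")
  invisible(x)
}

#' Uncorrected p-distances with pairwise deletion
#'
#' Distance between two taxa is the mismatch fraction over columns where both
#' have non-missing residues (`-` and `X` are missing). Errors if a pair
#' shares no columns.
#'
#' @param aln An [alignment] (or the `alignment` element of a
#'   [concatenate_partitions] result).
#' @return A `dist` object.
#' @export
p_distances <- function(aln) {
  if (inherits(aln, "supermatrix")) aln <- aln$alignment
  m <- aln_matrix(aln)
  ok <- !(m %in% c("-", "X"))
  dim(ok) <- dim(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- ok[i, ] & ok[j, ]
    if (!any(both)) {
      stop("taxa '", rownames(m)[i], "' and '", rownames(m)[j],
           "' share no scored columns")
    }
    d[i, j] <- d[j, i] <- mean(m[i, both] != m[j, both])
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree from p-distances
#'
#' Canonical neighbor joining (via `ape::nj`) on uncorrected p-distances with
#' pairwise deletion of missing data. Used as a fast validation harness for
#' signal-based partition selection, not as a substitute for model-based
#' inference.
#'
#' @param x An [alignment], [concatenate_partitions] result, or `dist`.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(x) {
  d <- if (inherits(x, "dist")) x else p_distances(x)
  ape::nj(d)
}

# Does `clade` form a bipartition (split) of the unrooted tree?
has_clade <- function(tree, clade) {
  tips <- tree$tip.label
  clade <- intersect(clade, tips)
  if (length(clade) <= 1 || length(clade) >= length(tips)) return(TRUE)
  parts <- ape::prop.part(tree)
  for (p in parts) {
    set <- tips[p]
    if (setequal(set, clade) || setequal(set, setdiff(tips, clade))) return(TRUE)
  }
  FALSE
}

#' Clade recovery rates for selected vs. rejected partitions
#'
#' Builds a neighbor-joining tree for every partition and tests whether the
#' clade appears as a bipartition; reports the recovery frequency per group.
#' Used to validate that partitions selected for high q(i) signal indeed
#' support the planted clade more often than rejected ones.
#'
#' @param partitions_selected,partitions_rejected Lists of [alignment]s.
#' @param clade Character vector of taxon labels.
#' @return Tibble with columns `group`, `n`, `n_recovered`, `rate`.
#' @export
clade_recovery <- function(partitions_selected, partitions_rejected, clade) {
  rate_for <- function(parts, label) {
    rec <- vapply(parts, function(a) has_clade(nj_tree(a), clade), logical(1))
    tibble(group = label, n = length(parts),
           n_recovered = sum(rec),
           rate = if (length(parts)) mean(rec) else NA_real_)
  }
  bind_rows(rate_for(partitions_selected, "selected"),
            rate_for(partitions_rejected, "rejected"))
}
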