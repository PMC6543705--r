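#' Read a FASTA file of contigs into a tibble
#'
#' Sequences are upper-cased on read. With `header_dialect = "spades"` the
#' record headers are expected to follow the SPAdes naming convention
#' `NODE_<i>_length_<L>_cov_<C>`; the length token must equal the actual
#' sequence length and the k-mer coverage token is parsed into the `coverage`
#' column. With `header_dialect = "plain"` coverage is `NA` (absent), which is
#' distinct from a parsed coverage of zero. A sidecar coverage table
#' (`id`, `coverage`) can be supplied instead for assemblies whose headers do
#' not encode coverage.
#'
#' @param path Path to a FASTA file.
#' @param header_dialect `"plain"` or `"spades"`.
#' @param coverage_table Optional data frame with columns `id` and `coverage`
#'   joined onto the result (plain dialect only).
#' @return A tibble with columns `id`, `seq`, `length`, `coverage`.
#' @export
read_fasta <- function(path, header_dialect = c("plain", "spades"),
                       coverage_table = NULL) {
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  check_fasta_shape(path)
  set <- Biostrings::readBStringSet(path)
  ids <- unname(sub("\\s.*$", "", names(set)))
  seqs <- unname(toupper(as.character(set)))
  out <- tibble(id = ids, seq = seqs, length = nchar(seqs),
                coverage = NA_real_)
  if (header_dialect == "spades") {
    m <- regmatches(out$id,
                    regexec("^NODE_[0-9]+_length_([0-9]+)_cov_([0-9.eE+-]+)$", out$id))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad)) {
      stop("header not in SPAdes dialect: ", out$id[which(bad)[1]])
    }
    hdr_len <- as.integer(vapply(m, `[`, character(1), 2L))
    cov <- as.numeric(vapply(m, `[`, character(1), 3L))
    mism <- hdr_len != out$length
    if (any(mism)) {
      stop("header length token (", hdr_len[which(mism)[1]],
           ") does not match sequence length (", out$length[which(mism)[1]],
           ") for ", out$id[which(mism)[1]])
    }
    out$coverage <- cov
  } else if (!is.null(coverage_table)) {
    ct <- as_tibble(coverage_table)
    stopifnot(all(c("id", "coverage") %in% names(ct)))
    out$coverage <- ct$coverage[match(out$id, ct$id)]
  }
  out
}

# Minimal structural validation so malformed files fail with a line number
# (Biostrings' own parser reports no position).
check_fasta_shape <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) stop("malformed FASTA (empty file): ", path)
  first <- nonempty[1]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA at line ", first, ": expected '>' header")
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' @param x A data frame with columns `id` and `seq` (a `seq_col` can name a
#'   different sequence column).
#' @param path Output path.
#' @param seq_col Name of the sequence column.
#' @param width Line wrap width.
#' @export
write_fasta <- function(x, path, seq_col = "seq", width = 70) {
  stopifnot(all(c("id", seq_col) %in% names(x)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x[[seq_col]][i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read motif models in minimal MEME text format
#'
#' Parses the MEME minimal motif format (version line, optional `ALPHABET`,
#' optional background frequency line, `MOTIF` blocks each followed by a
#' `letter-probability matrix:` header and `w` rows of 4 probabilities).
#' Each matrix row and the background must sum to 1 within `1e-6`.
#'
#' @param path Path to a minimal MEME motif file.
#' @return A list of [motif_model] objects, in file order.
#' @export
read_meme_minimal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  if (!any(grepl("^MEME version", lines))) {
    stop("not a minimal MEME motif file (missing 'MEME version' line): ", path)
  }
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    toks <- strsplit(lines[bg_at + 1], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    names(vals) <- toks[c(TRUE, FALSE)]
    if (!anyNA(vals)) background <- vals[DNA_BASES]
  }
  if (abs(sum(background) - 1) > 1e-6) {
    stop("background frequencies do not sum to 1: ", sum(background))
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0) stop("no MOTIF blocks in ", path)
  models <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    i <- motif_at[k]
    name <- strsplit(lines[i], "\\s+")[[1]][2]
    j <- i + 1
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j])) j <- j + 1
    if (j > length(lines)) stop("MOTIF '", name, "' has no letter-probability matrix")
    w_tok <- regmatches(lines[j], regexec("w=\\s*([0-9]+)", lines[j]))[[1]]
    rows <- list()
    j <- j + 1
    while (j <= length(lines) && nzchar(lines[j]) &&
           grepl("^[-0-9.eE+[:space:]]+$", lines[j])) {
      rows[[length(rows) + 1]] <- as.numeric(strsplit(lines[j], "\\s+")[[1]])
      j <- j + 1
    }
    mat <- do.call(rbind, rows)
    if (length(w_tok) == 2 && nrow(mat) != as.integer(w_tok[2])) {
      stop("MOTIF '", name, "': matrix has ", nrow(mat),
           " rows but header declares w=", w_tok[2])
    }
    colnames(mat) <- DNA_BASES
    models[[k]] <- motif_model(mat, background = background, name = name)
  }
  models
}

#' Construct an alignment object
#'
#' An alignment is a tibble with columns `taxon` and `seq` (equal-length
#' residue strings over the 20 amino acids plus `-` and `X`), carrying the
#' partition name as an attribute.
#'
#' @param taxa Character vector of taxon labels (unique).
#' @param seqs Character vector of aligned sequences, same length as `taxa`.
#' @param name Optional partition name.
#' @return A tibble of class `circlemat_aln`.
#' @export
alignment <- function(taxa, seqs, name = NULL) {
  stopifnot(length(taxa) == length(seqs), !anyDuplicated(taxa))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    off <- taxa[lens != lens[1]][1]
    stop("ragged alignment: taxon '", off, "' has length ", nchar(seqs[taxa == off][1]),
         " but '", taxa[1], "' has length ", lens[1])
  }
  out <- tibble(taxon = as.character(taxa), seq = toupper(as.character(seqs)))
  class(out) <- c("circlemat_aln", class(out))
  attr(out, "name") <- name
  out
}

#' @export
print.circlemat_aln <- function(x, ...) {
  nm <- attr(x, "name", exact = TRUE)
  cat("<alignment", if (!is.null(nm)) paste0(" '", nm, "'"), ": ",
      nrow(x), " taxa x ", if (nrow(x)) nchar(x$seq[1]) else 0, " columns>\n", sep = "")
  NextMethod()
}

#' Alignment as a character matrix (taxa x columns)
#' @param aln An [alignment] object.
#' @return Character matrix with taxon rownames.
#' @export
aln_matrix <- function(aln) {
  if (nrow(aln) == 0) return(matrix(character(0), nrow = 0, ncol = 0))
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$taxon
  m
}

aln_from_matrix <- function(m, name = NULL) {
  alignment(rownames(m), apply(m, 1, paste, collapse = ""), name = name)
}

#' Read a multiple alignment (aligned FASTA or relaxed PHYLIP)
#'
#' Enforces equal row lengths and preserves gap characters `-` and `X`.
#'
#' @param path Input path.
#' @param format `"fasta"` or `"phylip"` (relaxed, sequential).
#' @param name Optional partition name (defaults to the file base name).
#' @return An [alignment] tibble.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"), name = NULL) {
  format <- match.arg(format)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "fasta") {
    check_fasta_shape(path)
    set <- Biostrings::readBStringSet(path)
    return(alignment(sub("\\s.*$", "", names(set)), as.character(set), name = name))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr)) stop("malformed PHYLIP header: ", lines[1])
  ntax <- hdr[1]; nchar_aln <- hdr[2]
  toks <- unlist(strsplit(trimws(lines[-1]), "\\s+"))
  taxa <- character(ntax); seqs <- character(ntax)
  i <- 1
  for (t in seq_len(ntax)) {
    taxa[t] <- toks[i]; i <- i + 1
    acc <- ""
    while (nchar(acc) < nchar_aln) {
      if (i > length(toks)) stop("truncated PHYLIP: taxon '", taxa[t], "' has ",
                                 nchar(acc), "/", nchar_aln, " residues")
      acc <- paste0(acc, toks[i]); i <- i + 1
    }
    if (nchar(acc) != nchar_aln) stop("ragged alignment: taxon '", taxa[t],
                                      "' has length ", nchar(acc))
    seqs[t] <- acc
  }
  alignment(taxa, seqs, name = name)
}

#' Write a multiple alignment
#' @param aln An [alignment] object.
#' @param path Output path.
#' @param format `"fasta"` or `"phylip"` (relaxed, sequential).
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    return(write_fasta(tibble(id = aln$taxon, seq = aln$seq), path))
  }
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(nrow(aln), nchar(aln$seq[1])), con)
  writeLines(paste(aln$taxon, aln$seq), con)
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a tabular report as TSV
#' @param x A data frame.
#' @param path Output path.
#' @export
write_tsv_report <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a species-merge table for chimeric OTUs
#'
#' Expects a TSV with columns `chimera` and `members`, where `members` is a
#' comma-separated list of at least two species. Species must be distinct
#' within a row and no species may appear in two rows.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `chimera` (character) and `members` (list of
#'   character vectors).
#' @export
read_merge_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("chimera", "members") %in% names(raw)))
  members <- lapply(strsplit(raw$members, ","), trimws)
  validate_merge_table(tibble(chimera = raw$chimera, members = members))
}

validate_merge_table <- function(tbl) {
  for (i in seq_len(nrow(tbl))) {
    mem <- tbl$members[[i]]
    if (length(mem) < 2) stop("merge row '", tbl$chimera[i], "' has fewer than 2 species")
    if (anyDuplicated(mem)) stop("merge row '", tbl$chimera[i], "' repeats a species")
  }
  all_mem <- unlist(tbl$members)
  if (anyDuplicated(all_mem)) {
    stop("species appears in two merge rows: ",
         all_mem[duplicated(all_mem)][1])
  }
  tbl
}
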