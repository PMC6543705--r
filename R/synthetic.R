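#' Specification for a synthetic assembly
#'
#' Describes an assembly of linear contigs plus planted circular contigs.
#' Every planted circle carries an exact terminal direct repeat of
#' `k_repeat` bases (the first `k_repeat` bases of the contig equal its last
#' `k_repeat`). Long-circle body lengths are drawn from a Gaussian mixture
#' whose adjacent component means are `peak_spacing` bp apart (sd `peak_sd`),
#' rounded to integers and truncated to `long_length_range` -- emulating the
#' situation of estimating a fractional periodicity from integer contig
#' lengths. Short circles are optionally low complexity (homopolymer or
#' dinucleotide tracts). Mito circles embed the exact back-translation of a
#' reference protein; pseudogene circles carry a degraded copy with a planted
#' in-frame stop and/or a single-base deletion.
#'
#' @param n_linear,n_circles_short,n_circles_long Contig counts.
#' @param k_repeat Terminal repeat length (default 77 bp).
#' @param long_length_range Long-circle body length window (default 600-800).
#' @param peak_spacing Distance between adjacent mixture means (default 10.44
#'   bp, the observed periodicity of one turn of B-DNA).
#' @param peak_sd Component standard deviation (default 1.5 bp).
#' @param short_length_range Short-circle body length window.
#' @param linear_length_range Linear contig length window.
#' @param lowcomplexity_fraction_short Fraction of short circles built from
#'   low-complexity tracts (default 0.381).
#' @param motif_models List of [motif_model]s planted into long circles.
#' @param motif_rate Per-circle probability of planting each motif.
#' @param mito_refs Named character vector of reference protein sequences.
#' @param n_mito_circles,n_pseudogene_circles Counts of gene-bearing and
#'   degraded-copy circles.
#' @return List of class `assembly_sim_spec`.
#' @export
assembly_sim_spec <- function(n_linear = 200, n_circles_short = 100,
                              n_circles_long = 200, k_repeat = 77,
                              long_length_range = c(600, 800),
                              peak_spacing = 10.44, peak_sd = 1.5,
                              short_length_range = c(160, 499),
                              linear_length_range = c(200, 2000),
                              lowcomplexity_fraction_short = 0.381,
                              motif_models = list(), motif_rate = 1.0,
                              mito_refs = character(),
                              n_mito_circles = 0, n_pseudogene_circles = 0) {
  stopifnot(n_linear >= 0, n_circles_short >= 0, n_circles_long >= 0,
            k_repeat >= 1, peak_spacing > 0, peak_sd > 0,
            lowcomplexity_fraction_short >= 0, lowcomplexity_fraction_short <= 1,
            n_mito_circles >= 0, n_pseudogene_circles >= 0)
  if ((n_mito_circles > 0 || n_pseudogene_circles > 0) && length(mito_refs) == 0) {
    stop("mito or pseudogene circles requested but mito_refs is empty")
  }
  structure(as.list(environment()), class = "assembly_sim_spec")
}

draw_long_lengths <- function(n, range, spacing, sd) {
  # component means strictly inside the window so truncation does not shift
  # the outer peaks
  lo <- range[1] + spacing / 2
  k <- floor((range[2] - spacing / 2 - lo) / spacing)
  means <- lo + spacing * (0:k)
  out <- integer(0)
  while (length(out) < n) {
    m <- sample(means, n, replace = TRUE)
    l <- round(rnorm(n, mean = m, sd = sd))
    l <- l[l >= range[1] & l <= range[2]]
    out <- c(out, l)
  }
  out[seq_len(n)]
}

#' Generate integer circle lengths with a periodic multimodal distribution
#'
#' Draws lengths from a Gaussian mixture whose adjacent component means are
#' `spacing` bp apart (component sd `sd`), rounds to integers and truncates to
#' `range`. This is the length model used for long circles by
#' [gen_assembly]; exposing it directly allows spacing-estimator studies
#' without building full sequences.
#'
#' @param n Number of lengths.
#' @param range Length window (default 600-800 bp).
#' @param spacing Distance between adjacent component means (default 10.44).
#' @param sd Component standard deviation (default 1.5).
#' @param seed Integer seed.
#' @return Integer vector of `n` lengths.
#' @export
gen_circle_lengths <- function(n, range = c(600, 800), spacing = 10.44,
                               sd = 1.5, seed = 1) {
  with_seed(seed, draw_long_lengths(n, range, spacing, sd))
}

lowcomplexity_tract <- function(len) {
  if (runif(1) < 0.5) {
    strrep(sample(DNA_BASES, 1), len)
  } else {
    d <- paste(sample(DNA_BASES, 2, replace = FALSE), collapse = "")
    substr(strrep(d, ceiling(len / 2)), 1, len)
  }
}

plant_stop <- function(cds) {
  # replace one interior codon (never the first or last) with TAA
  n_codons <- nchar(cds) %/% 3
  j <- sample(2:(n_codons - 1), 1)
  paste0(substr(cds, 1, (j - 1) * 3), "TAA", substr(cds, j * 3 + 1, nchar(cds)))
}

plant_deletion <- function(cds) {
  # delete one base near the middle so the two halves sit in different frames
  pos <- (nchar(cds) %/% 2) + sample(-3:3, 1)
  paste0(substr(cds, 1, pos - 1), substr(cds, pos + 1, nchar(cds)))
}

#' Generate a synthetic assembly with known ground truth
#'
#' @param spec An [assembly_sim_spec].
#' @param seed Integer seed; the output is a pure function of `(spec, seed)`.
#' @return List with `contigs` (tibble `id`, `seq`, `length`, `coverage`) and
#'   `truth` (tibble with one row per contig recording every planted
#'   property: class, circularity, body length, low-complexity status, gene,
#'   pseudogene lesions and planted motif positions).
#' @export
gen_assembly <- function(spec, seed) {
  stopifnot(inherits(spec, "assembly_sim_spec"))
  with_seed(seed, {
    rows <- list()
    truths <- list()
    add <- function(class, body, is_lowc = FALSE, gene = NA_character_,
                    stop_planted = FALSE, indel_planted = FALSE,
                    motif_positions = integer(0)) {
      i <- length(rows) + 1L
      k <- spec$k_repeat
      contig <- paste0(body, substr(body, 1, k))
      is_circ <- TRUE
      if (class == "linear") { contig <- body; is_circ <- FALSE }
      cov <- round(stats::rlnorm(1, meanlog = if (is_circ) 3.5 else 2.0, sdlog = 0.6), 2)
      id <- sprintf("NODE_%d_length_%d_cov_%g", i, nchar(contig), cov)
      rows[[i]] <<- tibble(id = id, seq = contig, length = nchar(contig),
                           coverage = cov)
      truths[[i]] <<- tibble(id = id, class = class, is_circular = is_circ,
                             body_length = nchar(body),
                             contig_length = nchar(contig),
                             is_lowcomplexity = is_lowc, gene = gene,
                             stop_planted = stop_planted,
                             indel_planted = indel_planted,
                             motif_positions = list(motif_positions))
    }

    for (j in seq_len(spec$n_linear)) {
      len <- rint(spec$linear_length_range[1], spec$linear_length_range[2])
      add("linear", random_dna(len))
    }
    n_lowc <- rbinom(1, spec$n_circles_short, spec$lowcomplexity_fraction_short)
    for (j in seq_len(spec$n_circles_short)) {
      len <- rint(spec$short_length_range[1], spec$short_length_range[2])
      lowc <- j <= n_lowc
      body <- if (lowc) lowcomplexity_tract(len) else random_dna(len)
      add("circle_short", body, is_lowc = lowc)
    }
    long_lens <- draw_long_lengths(spec$n_circles_long, spec$long_length_range,
                                   spec$peak_spacing, spec$peak_sd)
    for (j in seq_len(spec$n_circles_long)) {
      body <- random_dna(long_lens[j])
      mpos <- integer(0)
      for (mm in spec$motif_models) {
        if (runif(1) < spec$motif_rate) {
          cons <- motif_consensus(mm)
          p <- sample(seq_len(nchar(body) - nchar(cons) + 1), 1)
          substr(body, p, p + nchar(cons) - 1) <- cons
          mpos <- c(mpos, p - 1L)
        }
      }
      add("circle_long", body, motif_positions = mpos)
    }
    gene_pool <- names(spec$mito_refs) %||% character(0)
    for (j in seq_len(spec$n_mito_circles)) {
      g <- gene_pool[1 + (j - 1) %% length(gene_pool)]
      cds <- backtranslate(spec$mito_refs[[g]])
      body <- paste0(cds, random_dna(rint(100, 300)))
      add("circle_mito", body, gene = g)
    }
    for (j in seq_len(spec$n_pseudogene_circles)) {
      g <- gene_pool[1 + (j - 1) %% length(gene_pool)]
      cds <- backtranslate(spec$mito_refs[[g]])
      lesion <- sample(c("stop", "indel", "both"), 1)
      if (lesion %in% c("stop", "both")) cds <- plant_stop(cds)
      if (lesion %in% c("indel", "both")) cds <- plant_deletion(cds)
      body <- paste0(cds, random_dna(rint(100, 300)))
      add("circle_pseudo", body, gene = g,
          stop_planted = lesion %in% c("stop", "both"),
          indel_planted = lesion %in% c("indel", "both"))
    }
    list(contigs = bind_rows(rows), truth = bind_rows(truths))
  })
}

#' Specification for a synthetic proteome mixture
#'
#' Emulates a parasite protein set contaminated with host- and
#' prokaryote-derived sequences. Contaminants are copies of database proteins
#' mutated to a controlled global percent identity (substitutions only, at
#' evenly spaced interior positions, so the planted identity is exact under
#' global alignment). Genuine parasite proteins share less than 40% identity
#' with every host and prokaryote sequence (enforced by rejection sampling)
#' and each has a diverged ortholog in the non-host metazoan reference set, as
#' real parasite proteins do.
#'
#' @param n_parasite,n_host,n_prokaryote Counts of genuine proteins and of
#'   host-/prokaryote-derived contaminants.
#' @param host_identity_range,prokaryote_identity_range Percent-identity
#'   windows for the contaminants (defaults 85-100 and 60-100).
#' @param other_identity Percent identity of the metazoan ortholog planted for
#'   each parasite protein (default 60).
#' @param mean_length Mean protein length in residues.
#' @param n_host_extra,n_prok_extra Additional database-only sequences.
#' @return List of class `proteome_sim_spec`.
#' @export
proteome_sim_spec <- function(n_parasite = 50, n_host = 15, n_prokaryote = 5,
                              host_identity_range = c(85, 100),
                              prokaryote_identity_range = c(60, 100),
                              other_identity = 60,
                              mean_length = 100,
                              n_host_extra = 10, n_prok_extra = 5) {
  stopifnot(all(host_identity_range >= 0 & host_identity_range <= 100),
            all(prokaryote_identity_range >= 0 & prokaryote_identity_range <= 100),
            mean_length > 20)
  structure(as.list(environment()), class = "proteome_sim_spec")
}

# Mutate `source` to an exact target percent identity: substitutions at evenly
# spaced interior positions (ends are left intact so local alignments retain
# the full span and identity equals matches / length).
mutate_to_identity <- function(source, identity) {
  L <- nchar(source)
  n_mut <- round((1 - identity / 100) * L)
  if (n_mut == 0) return(source)
  idx <- unique(round(seq(3, L - 2, length.out = n_mut)))
  chars <- seq_chars(source)
  for (i in idx) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# Pick a mutation count whose achieved identity 100 (L - n) / L lies inside
# [lo, hi] (or as close as the integer grid allows), uniformly at random
# among the feasible counts, then mutate.
mutate_into_range <- function(source, lo, hi) {
  L <- nchar(source)
  n_all <- 0:(L %/% 2)
  achieved <- 100 * (L - n_all) / L
  feasible <- n_all[achieved >= lo & achieved <= hi]
  if (length(feasible) == 0) {
    mid <- (lo + hi) / 2
    feasible <- n_all[which.min(abs(achieved - mid))]
  }
  n_mut <- if (length(feasible) == 1) feasible else sample(feasible, 1)
  mutate_to_identity(source, 100 * (L - n_mut) / L)
}

#' Generate a synthetic proteome mixture with known ground truth
#'
#' @param spec A [proteome_sim_spec].
#' @param seed Integer seed.
#' @return List with tibbles `queries` (the contaminated parasite set),
#'   `host_db`, `prok_db`, `other_db` and `truth` (query id, class, source
#'   and planted identity).
#' @export
gen_proteomes <- function(spec, seed) {
  stopifnot(inherits(spec, "proteome_sim_spec"))
  with_seed(seed, {
    plen <- function() max(30, round(rnorm(1, spec$mean_length, spec$mean_length / 8)))
    host_src <- tibble(id = sprintf("host_%03d", seq_len(spec$n_host + spec$n_host_extra)),
                       seq = vapply(seq_len(spec$n_host + spec$n_host_extra),
                                    function(i) random_protein(plen()), character(1)))
    prok_src <- tibble(id = sprintf("prok_%03d", seq_len(spec$n_prokaryote + spec$n_prok_extra)),
                       seq = vapply(seq_len(spec$n_prokaryote + spec$n_prok_extra),
                                    function(i) random_protein(plen()), character(1)))
    queries <- list(); truth <- list(); others <- list()
    for (i in seq_len(spec$n_parasite)) {
      repeat {
        s <- random_protein(plen())
        ids_vs <- c(host_src$seq, prok_src$seq)
        ok <- all(vapply(ids_vs, function(x) global_identity(s, x), numeric(1)) < 40)
        if (ok) break
      }
      qid <- sprintf("para_%03d", i)
      queries[[length(queries) + 1]] <- tibble(id = qid, seq = s)
      others[[length(others) + 1]] <-
        tibble(id = sprintf("metazoan_%03d", i),
               seq = mutate_to_identity(s, spec$other_identity))
      truth[[length(truth) + 1]] <- tibble(id = qid, class = "parasite",
                                           source = NA_character_,
                                           planted_identity = NA_real_)
    }
    for (i in seq_len(spec$n_host)) {
      src <- host_src[i, ]
      qid <- sprintf("hostc_%03d", i)
      mut <- mutate_into_range(src$seq, spec$host_identity_range[1],
                               spec$host_identity_range[2])
      queries[[length(queries) + 1]] <- tibble(id = qid, seq = mut)
      truth[[length(truth) + 1]] <-
        tibble(id = qid, class = "host_contam", source = src$id,
               planted_identity = 100 * mean(seq_chars(mut) == seq_chars(src$seq)))
    }
    for (i in seq_len(spec$n_prokaryote)) {
      src <- prok_src[i, ]
      qid <- sprintf("prokc_%03d", i)
      mut <- mutate_into_range(src$seq, spec$prokaryote_identity_range[1],
                               spec$prokaryote_identity_range[2])
      queries[[length(queries) + 1]] <- tibble(id = qid, seq = mut)
      truth[[length(truth) + 1]] <-
        tibble(id = qid, class = "prok_contam", source = src$id,
               planted_identity = 100 * mean(seq_chars(mut) == seq_chars(src$seq)))
    }
    list(queries = bind_rows(queries), host_db = host_src, prok_db = prok_src,
         other_db = bind_rows(others), truth = bind_rows(truth))
  })
}

#' Specification for synthetic alignment partitions
#'
#' Partitions carry a planted fraction of ingroup-synapomorphy columns: in a
#' signal column one residue is fixed across all ingroup taxa and absent from
#' the outgroup; the remaining columns are drawn iid from each taxon's
#' composition. With `composition_bias_strength = 0` all taxa share one
#' background composition; larger values draw per-taxon compositions from a
#' progressively less concentrated Dirichlet around the background, inflating
#' among-taxon compositional heterogeneity (RCFV). Missing cells (`-`) are
#' placed uniformly at rate `missing_fraction`.
#'
#' @param n_partitions Number of partitions.
#' @param n_taxa_ingroup,n_taxa_outgroup Taxon counts.
#' @param signal_fraction_per_partition Numeric vector (length
#'   `n_partitions`) of per-partition signal-column fractions.
#' @param missing_fraction Per-cell missing-data rate.
#' @param composition_bias_strength Dirichlet distortion strength (>= 0).
#' @param column_length_range Column-count window per partition.
#' @return List of class `partition_sim_spec`.
#' @export
partition_sim_spec <- function(n_partitions = 10, n_taxa_ingroup = 8,
                               n_taxa_outgroup = 8,
                               signal_fraction_per_partition = rep(0.05, 10),
                               missing_fraction = 0.1,
                               composition_bias_strength = 0,
                               column_length_range = c(200, 400)) {
  stopifnot(length(signal_fraction_per_partition) == n_partitions,
            all(signal_fraction_per_partition >= 0),
            all(signal_fraction_per_partition <= 1),
            missing_fraction >= 0, missing_fraction < 1,
            composition_bias_strength >= 0)
  structure(as.list(environment()), class = "partition_sim_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate synthetic alignment partitions with known ground truth
#'
#' @param spec A [partition_sim_spec].
#' @param seed Integer seed.
#' @return List with `partitions` (list of [alignment]s), `groups`
#'   (list `G1`, `G2` of taxon labels) and `truth` (tibble: partition,
#'   n_columns, n_signal, signal column indices).
#' @export
gen_partitions <- function(spec, seed) {
  stopifnot(inherits(spec, "partition_sim_spec"))
  with_seed(seed, {
    g1 <- sprintf("in_%02d", seq_len(spec$n_taxa_ingroup))
    g2 <- sprintf("out_%02d", seq_len(spec$n_taxa_outgroup))
    taxa <- c(g1, g2)
    bg <- rep(1 / 20, 20)
    comps <- lapply(taxa, function(t) {
      if (spec$composition_bias_strength == 0) bg
      else rdirichlet1(bg * 20 / spec$composition_bias_strength)
    })
    names(comps) <- taxa
    partitions <- list(); truth <- list()
    for (p in seq_len(spec$n_partitions)) {
      ncol_p <- rint(spec$column_length_range[1], spec$column_length_range[2])
      n_signal <- round(spec$signal_fraction_per_partition[p] * ncol_p)
      signal_cols <- sort(sample(ncol_p, n_signal))
      m <- matrix("", nrow = length(taxa), ncol = ncol_p, dimnames = list(taxa, NULL))
      for (t in taxa) {
        m[t, ] <- sample(AA_ALPHABET, ncol_p, replace = TRUE, prob = comps[[t]])
      }
      for (j in signal_cols) {
        a <- sample(AA_ALPHABET, 1)
        m[g1, j] <- a
        m[g2, j] <- sample(setdiff(AA_ALPHABET, a), length(g2), replace = TRUE)
      }
      if (spec$missing_fraction > 0) {
        miss <- matrix(runif(length(m)) < spec$missing_fraction, nrow = nrow(m))
        m[miss] <- "-"
      }
      nm <- sprintf("part_%03d", p)
      partitions[[p]] <- aln_from_matrix(m, name = nm)
      truth[[p]] <- tibble(partition = nm, n_columns = ncol_p,
                           n_signal = n_signal, signal_cols = list(signal_cols))
    }
    list(partitions = partitions, groups = list(G1 = g1, G2 = g2),
         truth = bind_rows(truth))
  })
}

#' Generate synthetic read pairs from circles or a concatenated precursor
#'
#' In `"circle"` mode both mates of every pair come from one circular
#' molecule (fragments may wrap the origin). In `"precursor"` mode fragments
#' are drawn from a single linear concatenation of the circles, so mates can
#' straddle circle junctions -- the signature an unprocessed multi-gene
#' precursor molecule would leave in paired-end data.
#'
#' @param circles Tibble with `id` and a sequence column (`trimmed_seq` if
#'   present, else `seq`) -- the circle bodies.
#' @param n_pairs Number of read pairs.
#' @param read_length Read length in bp.
#' @param insert_size Fragment length in bp.
#' @param mode `"circle"` or `"precursor"`.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `mate1`, `mate2`, `origin_label`.
#' @export
gen_read_pairs <- function(circles, n_pairs, read_length = 100,
                           insert_size = 250, mode = c("circle", "precursor"),
                           seed = 1) {
  mode <- match.arg(mode)
  seq_col <- if ("trimmed_seq" %in% names(circles)) "trimmed_seq" else "seq"
  bodies <- setNames(circles[[seq_col]], circles$id)
  stopifnot(all(nchar(bodies) >= read_length))
  with_seed(seed, {
    out <- vector("list", n_pairs)
    precursor <- paste(bodies, collapse = "")
    for (i in seq_len(n_pairs)) {
      if (mode == "circle") {
        ci <- sample(length(bodies), 1)
        body <- bodies[[ci]]
        doubled <- paste0(body, body)
        start <- sample(nchar(body), 1)
        frag <- substr(doubled, start, start + insert_size - 1)
        label <- names(bodies)[ci]
      } else {
        start <- sample(nchar(precursor) - insert_size + 1, 1)
        frag <- substr(precursor, start, start + insert_size - 1)
        label <- "precursor"
      }
      m1 <- substr(frag, 1, read_length)
      m2 <- revcomp(substr(frag, nchar(frag) - read_length + 1, nchar(frag)))
      out[[i]] <- tibble(id = sprintf("pair_%05d", i), mate1 = m1, mate2 = m2,
                         origin_label = label)
    }
    bind_rows(out)
  })
}
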