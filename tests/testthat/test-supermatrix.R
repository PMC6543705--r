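test_that("best-per-species selection maximises the summed group score", {
  set.seed(127)
  members <- vapply(1:3, function(i) rand_aa(80), character(1))

  single <- tibble::tibble(id = "only", seq = rand_aa(80))
  expect_equal(best_per_species(single, members)$id, "only")

  exact <- members[1]
  mutated <- make_mutant(members[1], 20)
  two <- tibble::tibble(id = c("mut", "exact"), seq = c(mutated, exact))
  expect_equal(best_per_species(two, members)$id, "exact")

  # 5 candidates vs 3 members: argmax of a brute-force all-pairs score sum
  cands <- tibble::tibble(id = sprintf("cand%d", 1:5),
                          seq = c(make_mutant(members[1], 5),
                                  make_mutant(members[2], 40),
                                  rand_aa(80), rand_aa(120),
                                  make_mutant(members[3], 10)))
  b62 <- local({ e <- new.env(); data("BLOSUM62", package = "Biostrings", envir = e); e$BLOSUM62 })
  brute <- vapply(cands$seq, function(q) {
    sum(vapply(members, function(m) {
      Biostrings::pairwiseAlignment(Biostrings::AAString(q), Biostrings::AAString(m),
                                    type = "local", substitutionMatrix = b62,
                                    gapOpening = 11, gapExtension = 1,
                                    scoreOnly = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(best_per_species(cands, members)$id, cands$id[which.max(brute)])
})

test_that("chimeric merging keeps the best-covered member under each label", {
  aln <- alignment(c("A_sp", "B_sp", "C_sp"),
                   c("ACDEFGHIKL", "ACDEF-----", "AC--------"),
                   name = "p1")
  mt <- tibble::tibble(chimera = "AB", members = list(c("A_sp", "B_sp")))
  merged <- merge_chimeric(list(aln), mt)[[1]]
  expect_setequal(merged$taxon, c("AB", "C_sp"))
  expect_equal(merged$seq[merged$taxon == "AB"], "ACDEFGHIKL")  # more residues

  # species not in any row pass through unchanged
  expect_true("C_sp" %in% merged$taxon)

  # the shipped 15-row merge table yields exactly 15 chimeric OTUs
  mt15 <- read_merge_table(system.file("extdata", "chimeric_taxa.tsv",
                                       package = "circlemat"))
  expect_equal(nrow(mt15), 15)
  species <- unlist(mt15$members)
  set.seed(131)
  seqs <- vapply(seq_along(species), function(i) rand_aa(50), character(1))
  parts <- list(alignment(species, seqs, name = "all_species"))
  merged15 <- merge_chimeric(parts, mt15)[[1]]
  expect_equal(sort(merged15$taxon), sort(mt15$chimera))
  expect_equal(nrow(merged15), 15)
})

test_that("gap trimming retains columns up to exactly half gaps and is idempotent", {
  aln <- alignment(paste0("t", 1:4),
                   c("AAAA", "AAA-", "AA--", "A---"))
  # column gap fractions 0, 0.25, 0.5, 0.75 -> three retained
  tr <- trim_columns(aln)
  expect_equal(nchar(tr$seq[1]), 3)
  expect_equal(aln_matrix(trim_columns(tr)), aln_matrix(tr))

  all_gap <- alignment(paste0("t", 1:3), c("A-", "C-", "D-"))
  expect_equal(nchar(trim_columns(all_gap)$seq[1]), 1)
})

test_that("invariant-column removal follows the non-missing residue count", {
  aln <- alignment(paste0("t", 1:4),
                   c("AAA", "AAA", "AAC", "A--"))
  # col1 AAAA invariant; col2 AAA- invariant (gap is missing); col3 AAC- varies
  out <- remove_invariant(aln)
  expect_equal(nchar(out$seq[1]), 1)
  expect_equal(aln_matrix(out)[, 1], c(t1 = "A", t2 = "A", t3 = "C", t4 = "-"))
  expect_equal(aln_matrix(remove_invariant(out)), aln_matrix(out))
})

test_that("concatenation fills absent taxa and accounts missing cells", {
  p1 <- alignment(c("a", "b"), c("ACDEFACDEF", "ACDEFACDEF"), name = "p1")
  sm1 <- concatenate_partitions(list(p1))
  expect_equal(sm1$total_positions, 10L)
  expect_equal(sm1$missing_fraction, 0)

  p2 <- alignment(c("c", "d"), c(strrep("K", 20), strrep("K", 20)), name = "p2")
  sm <- concatenate_partitions(list(p1, p2))
  expect_equal(sm$total_positions, 30L)
  expect_equal(sm$missing_fraction, 0.5)  # two disjoint taxon pairs
  expect_equal(sm$offsets$start, c(0, 10))
  expect_equal(sm$offsets$end, c(10, 30))

  # brute-force cell count on a ragged random fixture
  set.seed(137)
  parts <- lapply(1:4, function(i) {
    taxa <- sample(letters[1:6], sample(3:5, 1))
    alignment(taxa, vapply(taxa, function(t) {
      paste(sample(c("A", "C", "-", "X"), 12, TRUE), collapse = "")
    }, character(1)), name = paste0("p", i))
  })
  sm4 <- concatenate_partitions(parts)
  m <- aln_matrix(sm4$alignment)
  expect_equal(sm4$missing_fraction, sum(m %in% c("-", "X")) / length(m))
  expect_true(all(diff(sm4$offsets$start) > 0))
  expect_equal(sm4$offsets$start[-1], sm4$offsets$end[-4])
})

test_that("RCFV matches hand computation and its invariances", {
  ident <- alignment(c("a", "b", "c"), rep("ACDEFG", 3))
  expect_equal(rcfv(ident)$rcfv, 0)

  two_state <- alignment(c("a", "b"), c("AAAA", "CCCC"))
  expect_equal(rcfv(two_state)$rcfv, 1.0)  # 2 * (0.5 + 0.5) / 2

  set.seed(139)
  taxa <- paste0("t", 1:6)
  m <- matrix(sample(strsplit("ACDEFGHIKL", "")[[1]], 6 * 40, TRUE), 6, 40,
              dimnames = list(taxa, NULL))
  aln <- circlemat:::aln_from_matrix(m)
  v0 <- rcfv(aln)$rcfv
  perm_taxa <- circlemat:::aln_from_matrix(m[sample(6), ])
  perm_cols <- circlemat:::aln_from_matrix(m[, sample(40)])
  expect_equal(rcfv(perm_taxa)$rcfv, v0)
  expect_equal(rcfv(perm_cols)$rcfv, v0)
})

test_that("RCFV grows with planted compositional bias and gates the filter", {
  mean_rcfv <- function(bias) {
    vals <- vapply(1:10, function(s) {
      sp <- partition_sim_spec(n_partitions = 1,
                               signal_fraction_per_partition = 0,
                               missing_fraction = 0,
                               composition_bias_strength = bias,
                               column_length_range = c(300, 300))
      rcfv(gen_partitions(sp, 140 + s)$partitions[[1]])$rcfv
    }, numeric(1))
    mean(vals)
  }
  ladder <- vapply(c(0, 1, 4, 16), mean_rcfv, numeric(1))
  expect_true(all(diff(ladder) > 0))

  # the filter discards strictly above the cutoff
  lo <- alignment(c("a", "b"), c("AAAA", "AAAA"), name = "lo")
  hi <- alignment(c("a", "b"), c("AAAA", "CCCC"), name = "hi")
  fl <- rcfv_filter(list(lo, hi), rcfv_max = 0.115)
  expect_equal(fl$report$kept, c(TRUE, FALSE))
})

test_that("Dayhoff recoding collapses the alphabet to six groups", {
  all20 <- "ACDEFGHIKLMNPQRSTVWY"
  rec <- dayhoff_recode(all20)
  expect_equal(length(unique(strsplit(rec, "")[[1]])), 6)

  # within-group substitution leaves the recoded sequence unchanged
  expect_equal(dayhoff_recode("KIWI"), dayhoff_recode("KLWL"))
  expect_equal(dayhoff_recode("A-C-X"), "1-6-X")
})
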