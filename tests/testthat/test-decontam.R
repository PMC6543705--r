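# Shared fixtures: decoy databases built from deterministic mutants whose
# local-alignment identity is exactly the planted match fraction.

test_that("step 1 removes prokaryote best hits from 50% identity upward", {
  set.seed(97)
  prok_base <- rand_aa(100)
  prok_db <- tibble::tibble(id = "prok1", seq = prok_base)
  other_db <- tibble::tibble(id = "oth1", seq = rand_aa(100))
  host_db <- tibble::tibble(id = character(), seq = character())

  idents <- 40:60
  queries <- tibble::tibble(
    id = sprintf("q%02d", idents),
    seq = vapply(idents, function(i) make_mutant(prok_base, 100 - i), character(1)))
  removed <- step1_prokaryote(queries, prok_db, host_db, other_db)
  removed_ident <- idents[queries$id %in% removed]
  expect_equal(min(removed_ident), 50)
  expect_setequal(removed_ident, 50:60)
})

test_that("step 2 requires a strict host score win and identity above 70%", {
  set.seed(101)
  host_base <- rand_aa(100)
  host_db <- tibble::tibble(id = "host1", seq = host_base)
  other_db <- tibble::tibble(id = "oth1", seq = rand_aa(100))
  prok_db <- tibble::tibble(id = character(), seq = character())

  idents <- 65:75
  queries <- tibble::tibble(
    id = sprintf("q%02d", idents),
    seq = vapply(idents, function(i) make_mutant(host_base, 100 - i), character(1)))
  removed <- step2_host_besthit(queries, host_db, prok_db, other_db)
  removed_ident <- idents[queries$id %in% removed]
  expect_equal(min(removed_ident), 71)     # strictly above 70
  expect_setequal(removed_ident, 71:75)

  # a query whose best hit is a non-host metazoan is retained regardless
  meta_base <- other_db$seq[1]
  near_meta <- tibble::tibble(id = "qm", seq = make_mutant(meta_base, 5))
  expect_length(step2_host_besthit(near_meta, host_db, prok_db, other_db), 0)
})

test_that("step 3 captures candidates that top a host query at >= 80% identity", {
  set.seed(103)
  host_base <- rand_aa(100)
  host_db <- tibble::tibble(id = "host1", seq = host_base)
  other_db <- tibble::tibble(id = "oth1", seq = rand_aa(100))

  idents <- 75:85
  candidates <- tibble::tibble(
    id = sprintf("c%02d", idents),
    seq = vapply(idents, function(i) make_mutant(host_base, 100 - i), character(1)))
  # one candidate per run so each identity is tested as the top match
  removed_ident <- idents[vapply(seq_along(idents), function(k) {
    length(step3_reciprocal(host_db, candidates[k, ], other_db)) == 1
  }, logical(1))]
  expect_equal(min(removed_ident), 80)
  expect_setequal(removed_ident, 80:85)

  # a candidate outranked by a reference sequence is retained
  outranked <- tibble::tibble(id = "far", seq = rand_aa(100))
  other_close <- tibble::tibble(id = "oth_close", seq = make_mutant(host_base, 2))
  expect_length(step3_reciprocal(host_db, outranked, other_close), 0)
})

test_that("the cascade removes planted contaminants and spares the parasite", {
  spec <- proteome_sim_spec(n_parasite = 40, n_host = 10, n_prokaryote = 4,
                            host_identity_range = c(85, 100),
                            prokaryote_identity_range = c(60, 100))
  g <- gen_proteomes(spec, 107)
  rep <- run_cascade(g$queries, g$host_db, g$prok_db, g$other_db)

  prok_ids <- g$truth$id[g$truth$class == "prok_contam"]
  host_ids <- g$truth$id[g$truth$class == "host_contam"]
  para_ids <- g$truth$id[g$truth$class == "parasite"]
  removed <- c(rep$removed_step1, rep$removed_step2, rep$removed_step3)
  expect_true(all(prok_ids %in% removed))
  expect_true(all(host_ids %in% removed))
  false_removal <- mean(!para_ids %in% rep$retained)
  expect_lte(false_removal, 0.01)

  # the four sets partition the input
  expect_setequal(c(removed, rep$retained), g$queries$id)
  expect_equal(length(removed) + length(rep$retained), nrow(g$queries))

  # no randomness: identical rerun
  rep2 <- run_cascade(g$queries, g$host_db, g$prok_db, g$other_db)
  expect_identical(tidy(rep), tidy(rep2))

  # empty host database: steps 2 and 3 remove nothing
  empty_host <- tibble::tibble(id = character(), seq = character())
  rep0 <- run_cascade(g$queries, empty_host, g$prok_db, g$other_db)
  expect_length(rep0$removed_step2, 0)
  expect_length(rep0$removed_step3, 0)
})

test_that("raising identity thresholds never enlarges the removed set", {
  spec <- proteome_sim_spec(n_parasite = 10, n_host = 6, n_prokaryote = 3)
  g <- gen_proteomes(spec, 109)
  strict <- cascade_config(prok_min_identity = 60, host_min_identity_step2 = 80,
                           host_min_identity_step3 = 90)
  rep_def <- run_cascade(g$queries, g$host_db, g$prok_db, g$other_db)
  rep_str <- run_cascade(g$queries, g$host_db, g$prok_db, g$other_db, strict)
  removed_def <- setdiff(g$queries$id, rep_def$retained)
  removed_str <- setdiff(g$queries$id, rep_str$retained)
  expect_true(all(removed_str %in% removed_def))
})

test_that("identity counts gaps in the denominator", {
  # 30 residues vs the same with one internal deletion: the full-span local
  # alignment has 30 columns, 29 identities -> 100 * 29 / 30
  set.seed(113)
  a <- rand_aa(30)
  b <- paste0(substr(a, 1, 14), substr(a, 16, 30))
  hit <- circlemat:::align_local(a, b, protein_scheme())
  expect_equal(hit$identity, 100 * 29 / 30, tolerance = 1e-9)
})
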