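test_that("q(i) matches its analytic cases", {
  g <- group_assignment(paste0("i", 1:10), paste0("o", 1:10))

  # ingroup monomorphic for a residue the outgroup lacks: q = 1 exactly
  set.seed(149)
  aln1 <- alignment(c(paste0("i", 1:10), paste0("o", 1:10)),
                    c(rep("K", 10),
                      sample(setdiff(strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]], "K"),
                             10, TRUE)))
  q1 <- compute_q(aln1, g)
  expect_true(q1$considered)
  expect_identical(q1$q, 1)
  expect_equal(q1$a, "K")

  # identical frequency profiles: q = 0
  aln0 <- alignment(c(paste0("i", 1:4), paste0("o", 1:4)),
                    c("A", "A", "C", "C", "A", "A", "C", "C"))
  q0 <- compute_q(aln0, group_assignment(paste0("i", 1:4), paste0("o", 1:4)))
  expect_equal(q0$q, 0)

  # hand computation: G1 = AAAC, G2 = ACCC -> q = 0.75 - 0.25 = 0.5, a = A
  alnh <- alignment(c(paste0("i", 1:4), paste0("o", 1:4)),
                    c("A", "A", "A", "C", "A", "C", "C", "C"))
  qh <- compute_q(alnh, group_assignment(paste0("i", 1:4), paste0("o", 1:4)))
  expect_equal(qh$q, 0.5)
  expect_equal(qh$a, "A")
})

test_that("columns with over half missing data in either group are skipped", {
  g <- group_assignment(paste0("i", 1:4), paste0("o", 1:4))
  # 2/4 missing in G1 (exactly half) -> considered; 3/4 -> not
  half <- alignment(c(paste0("i", 1:4), paste0("o", 1:4)),
                    c("A", "A", "-", "X", "C", "C", "C", "C"))
  over <- alignment(c(paste0("i", 1:4), paste0("o", 1:4)),
                    c("A", "-", "-", "X", "C", "C", "C", "C"))
  expect_true(compute_q(half, g)$considered)
  expect_false(compute_q(over, g)$considered)
  expect_true(is.na(compute_q(over, g)$q))

  # q is invariant under taxon reordering
  set.seed(151)
  taxa <- c(paste0("i", 1:5), paste0("o", 1:5))
  m <- matrix(sample(c("A", "C", "D", "-"), 10 * 30, TRUE), 10, 30,
              dimnames = list(taxa, NULL))
  a1 <- circlemat:::aln_from_matrix(m)
  a2 <- circlemat:::aln_from_matrix(m[sample(10), ])
  g5 <- group_assignment(paste0("i", 1:5), paste0("o", 1:5))
  expect_equal(compute_q(a1, g5)$q, compute_q(a2, g5)$q)
})

test_that("q responds monotonically to ingroup fixation", {
  # the non-fixed ingroup residues are spread across distinct amino acids so
  # increasing the fixation of K is the only growing signal
  g <- group_assignment(paste0("i", 1:8), paste0("o", 1:8))
  others <- c("D", "E", "F", "G", "H", "I", "L", "M")
  qs <- vapply(0:8, function(k) {
    col <- c(rep("K", k), others[seq_len(8 - k)], rep("C", 8))
    aln <- alignment(c(paste0("i", 1:8), paste0("o", 1:8)), col)
    compute_q(aln, g)$q
  }, numeric(1))
  expect_true(all(diff(qs) >= 0))
  expect_equal(qs[9], 1)
})

test_that("partition selection applies the >= 3% rule inclusively", {
  parts <- list(make_flagged_partition(1000, 50, name = "a"),   # 5%
                make_flagged_partition(1000, 20, name = "b"),   # 2%
                make_flagged_partition(1000, 30, name = "c"))   # 3% boundary
  g <- group_assignment(paste0("in", 1:5), paste0("out", 1:5))
  sel <- select_partitions(parts, g)
  expect_equal(sel$report$selected, c(TRUE, FALSE, TRUE))
  expect_equal(sel$n_selected, 2)
  expect_equal(sel$selected_positions, 2000)

  # q > 0.5 is strict: a column at exactly 0.5 is not flagged
  taxa <- c(paste0("in", 1:4), paste0("out", 1:4))
  aln <- alignment(taxa, c("A", "A", "A", "C", "A", "C", "C", "C"))
  s <- select_partitions(list(aln), group_assignment(paste0("in", 1:4),
                                                     paste0("out", 1:4)))
  expect_equal(s$report$n_flagged, 0L)
})

test_that("selection agrees with generator truth across seeds", {
  for (s in 1:5) {
    sp <- partition_sim_spec(n_partitions = 6, n_taxa_ingroup = 8,
                             n_taxa_outgroup = 8,
                             signal_fraction_per_partition = c(0, 0, 0.05, 0.05, 0.1, 0.2),
                             missing_fraction = 0.05,
                             column_length_range = c(250, 350))
    gp <- gen_partitions(sp, 160 + s)
    g <- group_assignment(gp$groups$G1, gp$groups$G2)
    sel <- select_partitions(gp$partitions, g)
    planted <- sp$signal_fraction_per_partition
    expect_true(all(sel$report$selected[planted >= 0.05]))
    expect_true(all(!sel$report$selected[planted == 0]))
  }
})

test_that("NJ recovers additive topologies and exact 3-taxon branch lengths", {
  set.seed(163)
  for (i in 1:5) {
    tr <- ape::rtree(4, br = function(n) runif(n, 0.05, 0.5))
    d <- as.dist(ape::cophenetic.phylo(tr))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj_tree(d))), 0)
  }

  # three taxa: branch lengths solve the three-point formulas
  dm <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(as.dist(dm))
  lens <- setNames(t3$edge.length[order(t3$edge[, 2])][seq_len(3)], t3$tip.label)
  expect_equal(unname(lens["a"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(lens["b"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(lens["c"]), (0.4 + 0.5 - 0.3) / 2)
})

test_that("NJ agrees with brute-force minimum evolution on 5-taxon additive data", {
  all15 <- phangorn::allTrees(5, rooted = FALSE, tip.label = paste0("t", 1:5))
  set.seed(167)
  for (i in 1:20) {
    tr <- ape::rtree(5, br = function(n) runif(n, 0.05, 0.4))
    tr$tip.label <- paste0("t", 1:5)
    dm <- ape::cophenetic.phylo(tr)
    fit_len <- vapply(all15, function(topo) {
      f <- phangorn::nnls.tree(dm, topo, method = "unrooted")
      sum(pmax(f$edge.length, 0))
    }, numeric(1))
    me_best <- all15[[which.min(fit_len)]]
    expect_equal(as.numeric(ape::dist.topo(me_best, nj_tree(as.dist(dm)))), 0)
  }
})

test_that("selected partitions recover the planted clade at least as often", {
  recov <- lapply(1:5, function(s) {
    sp <- partition_sim_spec(n_partitions = 30, n_taxa_ingroup = 8,
                             n_taxa_outgroup = 8,
                             signal_fraction_per_partition =
                               rep(c(0, 0.08), each = 15),
                             missing_fraction = 0,
                             column_length_range = c(250, 300))
    gp <- gen_partitions(sp, 170 + s)
    g <- group_assignment(gp$groups$G1, gp$groups$G2)
    sel <- select_partitions(gp$partitions, g)
    clade_recovery(gp$partitions[sel$report$selected],
                   gp$partitions[!sel$report$selected],
                   clade = gp$groups$G1)
  })
  sel_rate <- mean(vapply(recov, function(r) r$rate[r$group == "selected"], numeric(1)))
  rej_rate <- mean(vapply(recov, function(r) r$rate[r$group == "rejected"], numeric(1)))
  expect_gt(sel_rate, rej_rate)

  # a clade of all taxa is trivially present
  sp1 <- partition_sim_spec(n_partitions = 1, signal_fraction_per_partition = 0,
                            missing_fraction = 0)
  gp1 <- gen_partitions(sp1, 180)
  all_taxa <- gp1$partitions[[1]]$taxon
  expect_equal(clade_recovery(gp1$partitions, list(), all_taxa)$rate[1], 1)

  # random partitions recover a balanced 8-taxon clade rarely
  sp_null <- partition_sim_spec(n_partitions = 20,
                                signal_fraction_per_partition = rep(0, 20),
                                missing_fraction = 0,
                                column_length_range = c(250, 300))
  gp_null <- gen_partitions(sp_null, 181)
  null_rate <- clade_recovery(gp_null$partitions, list(),
                              gp_null$groups$G1)$rate[1]
  expect_lt(null_rate, 0.3)
})
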