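test_that("terminal-repeat classifier finds and trims circular contigs", {
  set.seed(42)
  x <- rand_dna(800)
  contig <- paste0(x, substr(x, 1, 77))  # X + R, R = first 77 bases
  lin <- rand_dna(2000)
  tb <- detect_circles(tibble::tibble(id = c("a", "b"), seq = c(contig, lin)))
  expect_equal(tb$is_circular, c(TRUE, FALSE))
  expect_equal(tb$trimmed_length[1], nchar(contig) - 77L)
  expect_equal(tb$trimmed_seq[1], x)
  expect_equal(tb$trimmed_seq[2], lin)

  # a 76-nt repeat falls below the default threshold
  y <- rand_dna(800)
  c76 <- paste0(y, substr(y, 1, 76))
  expect_false(detect_circles(tibble::tibble(id = "c", seq = c76))$is_circular)

  # contigs shorter than 2k cannot be circular (classified linear, no error)
  tiny <- strrep("A", 100)
  expect_false(detect_circles(tibble::tibble(id = "t", seq = tiny))$is_circular)
})

test_that("classification matches the generator truth table exactly", {
  spec <- assembly_sim_spec(n_linear = 150, n_circles_short = 75,
                            n_circles_long = 75)
  a <- gen_assembly(spec, seed = 13)
  dc <- detect_circles(a$contigs)
  expect_equal(dc$is_circular, a$truth$is_circular)
  expect_equal(dc$trimmed_length[dc$is_circular],
               a$truth$body_length[a$truth$is_circular])
})

test_that("circle detection is idempotent and rotation invariant", {
  set.seed(3)
  body <- rand_dna(600)
  k <- 77
  # trimming never removes more than k bases, and re-running classifies the
  # trimmed circle by its own borders
  contig <- paste0(body, substr(body, 1, k))
  d1 <- detect_circles(tibble::tibble(id = "c", seq = contig))
  expect_equal(nchar(contig) - d1$trimmed_length, k)
  d2 <- detect_circles(tibble::tibble(id = "c", seq = d1$trimmed_seq))
  expect_false(d2$is_circular)  # a random body has no 77-nt border of its own

  # any rotation of the body, re-wrapped, is still detected
  for (off in c(1, 150, 599)) {
    rot <- paste0(substr(body, off + 1, nchar(body)), substr(body, 1, off))
    wrapped <- paste0(rot, substr(rot, 1, k))
    expect_true(detect_circles(tibble::tibble(id = "r", seq = wrapped))$is_circular)
  }
})

test_that("pool split uses a strict <500 boundary and reports medians", {
  tb <- tibble::tibble(id = paste0("c", 1:4),
                       trimmed_length = c(300, 499, 500, 702),
                       is_circular = TRUE)
  pools <- split_pools(tb)
  expect_equal(pools$short$trimmed_length, c(300, 499))
  expect_equal(pools$long$trimmed_length, c(500, 702))

  tb2 <- tibble::tibble(id = paste0("c", 1:3),
                        trimmed_length = c(500, 702, 900), is_circular = TRUE)
  expect_equal(split_pools(tb2)$summary$median_length[2], 702)

  empty <- split_pools(tibble::tibble(id = character(),
                                      trimmed_length = numeric(),
                                      is_circular = logical()))
  expect_equal(empty$summary$n, c(0L, 0L))
  expect_true(all(is.na(empty$summary$median_length)))
})

test_that("DUST fraction behaves at the extremes and matches a per-window oracle", {
  expect_equal(dust_fraction(strrep("A", 500)), 1.0)

  # cycle through all 64 trinucleotides evenly: near-uniform triplet counts
  tri <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                           c("A","C","G","T")), 1, paste, collapse = "")
  debruijnish <- paste(tri, collapse = "")
  expect_equal(dust_fraction(debruijnish), 0.0)

  set.seed(8)
  half <- paste0(strrep("T", 500), rand_dna(500))
  frac <- dust_fraction(half)
  expect_gte(frac, 0.45); expect_lte(frac, 0.55)
  # per-base mask equality with the naive recomputation
  expect_equal(circlemat:::dust_mask(half), dust_mask_oracle(half))
  mixed <- paste0(rand_dna(150), strrep("AT", 60), rand_dna(150))
  expect_equal(circlemat:::dust_mask(mixed), dust_mask_oracle(mixed))
})

test_that("peak spacing recovers exact combs and flags unimodal data", {
  comb <- rep(seq(600, 790, by = 10), each = 100)
  ps <- peak_spacing(comb)
  expect_equal(ps$spacing, 10.0, tolerance = 0.05 / 10)

  set.seed(2)
  uni <- round(rnorm(2000, 700, 3))
  psu <- peak_spacing(uni)
  expect_true(is.na(psu$spacing))
  expect_lt(psu$n_peaks, 2)

  expect_error(peak_spacing(c(650, 700)), "at least 200")
})

test_that("peak-spacing estimator has small bias and RMSE at study scale", {
  ests <- vapply(1:20, function(s) {
    lens <- gen_circle_lengths(3000, spacing = 10.44, sd = 1.5, seed = 4000 + s)
    peak_spacing(lens)$spacing
  }, numeric(1))
  expect_lt(abs(mean(ests) - 10.44), 0.1)          # bias
  expect_lt(sqrt(mean((ests - 10.44)^2)), 0.3)     # RMSE
})

test_that("KS statistic and p-value follow the asymptotic series", {
  x <- rnorm(50)
  same <- ks_compare(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)

  disjoint <- ks_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint$D, 1)

  # p at D = 0.5, n1 = n2 = 20 matches direct series summation to 1e-9
  ne <- 20 * 20 / 40
  lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * 0.5
  expect_equal(circlemat:::ks_series(lam), ks_series_oracle(lam),
               tolerance = 1e-9)

  # and tracks R's asymptotic two-sample KS test on continuous data (the
  # Stephens small-sample correction in lambda makes p slightly smaller than
  # R's plain sqrt(n_e) * D version, so compare loosely)
  set.seed(31)
  a <- rnorm(120); b <- rnorm(150, 0.3)
  ours <- ks_compare(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(ours$D, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 0.25)
  expect_lte(ours$p_value, ref$p.value)
})

test_that("KS p-values are calibrated under the null", {
  set.seed(77)
  reject <- vapply(1:2000, function(i) {
    ks_compare(rnorm(100), rnorm(100))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})
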