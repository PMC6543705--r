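# Independent oracles used by the test suite. These reimplement the checked
# quantities by brute force and never call the code paths they verify.

rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
rand_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE), collapse = "")
}

# Plain quadratic-space affine-gap Smith-Waterman (gap of length L costs
# gap_open + gap_extend * L); N is a mismatch against everything.
sw_oracle <- function(a, b, match = 1, mismatch = -2, gap_open = 5, gap_extend = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_extend, H[i, j - 1] - gap_open - gap_extend)
      FF[i, j] <- max(FF[i - 1, j] - gap_extend, H[i - 1, j] - gap_open - gap_extend)
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Exhaustive word enumeration for PWM p-values on the discretised score scale.
pwm_pvalue_enum <- function(model, score) {
  w <- model$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  tot <- rep(0L, nrow(words))
  prob <- rep(1, nrow(words))
  for (i in seq_len(w)) {
    tot <- tot + model$score_int[i, words[, i]]
    prob <- prob * model$background[words[, i]]
  }
  sum(prob[tot >= round(score / model$eps)])
}

# Connected components by boolean matrix powering (transitive closure).
components_oracle <- function(adj) {
  n <- nrow(adj)
  R <- adj | diag(TRUE, n)
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[which(R[i, ])] <- next_id
    }
  }
  comp
}

# Per-window recomputation of the DUST mask (no incremental updates).
dust_mask_oracle <- function(seq, window = 64, level = 2.0) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 3) return(rep(FALSE, n))
  code <- match(chars, c("A", "C", "G", "T"))
  tri <- (code[1:(n - 2)] - 1) * 16 + (code[2:(n - 1)] - 1) * 4 + code[3:n]
  w <- min(window, n)
  masked <- rep(FALSE, n)
  for (s in seq_len(n - w + 1)) {
    tw <- tri[s:(s + w - 3)]
    tw <- tw[!is.na(tw)]
    cnt <- table(tw)
    score <- sum(cnt * (cnt - 1)) / 2 / (w - 3)
    if (score > level) masked[s:(s + w - 1)] <- TRUE
  }
  masked
}

# Histogram-mode spacing oracle: a mode is a 1-bp bin that is the strict
# argmax of its +/- 4 bp neighborhood and holds at least 30% of the maximum
# count; returns the mean difference of mode positions.
hist_mode_spacing <- function(lengths, window = c(600, 800), radius = 4) {
  x <- lengths[lengths >= window[1] & lengths <= window[2]]
  bins <- tabulate(round(x) - window[1] + 1L, nbins = window[2] - window[1] + 1L)
  n <- length(bins)
  is_mode <- vapply(seq_len(n), function(i) {
    nb <- bins[max(1, i - radius):min(n, i + radius)]
    bins[i] == max(nb) && sum(nb == bins[i]) == 1 && bins[i] >= 0.3 * max(bins)
  }, logical(1))
  pos <- window[1] - 1L + which(is_mode)
  mean(diff(pos))
}

# Direct high-precision evaluation of the KS asymptotic series.
ks_series_oracle <- function(lambda, terms = 10000) {
  j <- terms:1
  sum(2 * (-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
}

# Conservative amino-acid substitution map (BLOSUM62 scores >= -1) so planted
# percent identity survives local alignment without end trimming.
CONSERVATIVE_SUB <- c(A = "S", C = "A", D = "E", E = "D", F = "Y", G = "A",
                      H = "N", I = "V", K = "R", L = "M", M = "L", N = "D",
                      P = "A", Q = "E", R = "K", S = "T", T = "S", V = "I",
                      W = "Y", Y = "F")

# Mutate `n_mut` evenly spaced interior positions with conservative
# substitutions; identity of the mutant to the source is exactly
# (L - n_mut) / L under full-span alignment.
make_mutant <- function(seq, n_mut) {
  if (n_mut == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  idx <- unique(round(seq(3, L - 2, length.out = n_mut)))
  stopifnot(length(idx) == n_mut)
  chars[idx] <- CONSERVATIVE_SUB[chars[idx]]
  paste(chars, collapse = "")
}

# Minimal MEME motif text for a list of probability matrices.
meme_text <- function(mats, background = c(A = .25, C = .25, G = .25, T = .25)) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "Background letter frequencies",
           paste(names(background), background, collapse = " "), "")
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    out <- c(out,
             paste0("MOTIF motif_", k),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     nrow(m)),
             apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
             "")
  }
  out
}

# A simple probability matrix concentrated on a consensus word.
consensus_pwm <- function(word, major = 0.97) {
  letters <- strsplit(word, "")[[1]]
  m <- matrix((1 - major) / 3, length(letters), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(letters)) m[i, letters[i]] <- major
  m
}

# Build an amino-acid alignment partition where exactly `n_flagged` columns
# are perfect ingroup synapomorphies and the rest carry no group signal.
make_flagged_partition <- function(n_cols, n_flagged, n_in = 5, n_out = 5,
                                   name = "p") {
  taxa <- c(paste0("in", seq_len(n_in)), paste0("out", seq_len(n_out)))
  m <- matrix("G", length(taxa), n_cols, dimnames = list(taxa, NULL))
  if (n_flagged > 0) {
    for (j in seq_len(n_flagged)) {
      m[seq_len(n_in), j] <- "A"
      m[n_in + seq_len(n_out), j] <- "C"
    }
  }
  circlemat::alignment(taxa, apply(m, 1, paste, collapse = ""), name = name)
}
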