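#' Position weight matrix motif model
#'
#' A PWM over ACGT with background frequencies. Words are scored as log-odds,
#' `sum_i log2((matrix[i, x_i] + pseudocount * bg[x_i]) / bg[x_i])`, and the
#' score-to-p-value map is computed exactly by dynamic programming over
#' positions with scores discretised to `eps` bits (FIMO semantics: the
#' p-value of a score is the probability that an iid background word scores at
#' least as high).
#'
#' @param matrix A `w x 4` matrix of letter probabilities (columns A, C, G, T;
#'   each row must sum to 1 within 1e-6).
#' @param background Background letter frequencies (sum to 1 within 1e-6).
#' @param pseudocount Pseudocount weight added as `pseudocount * bg` (default
#'   1e-3).
#' @param name Optional motif name.
#' @param eps Score discretisation step in bits (default 1e-3).
#' @return Object of class `motif_model`.
#' @export
motif_model <- function(matrix, background = c(A = .25, C = .25, G = .25, T = .25),
                        pseudocount = 1e-3, name = NULL, eps = 1e-3) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4)
  colnames(matrix) <- DNA_BASES
  row_sums <- rowSums(matrix)
  if (any(abs(row_sums - 1) > 1e-6)) {
    stop("letter-probability row ", which(abs(row_sums - 1) > 1e-6)[1],
         " sums to ", row_sums[abs(row_sums - 1) > 1e-6][1], ", not 1")
  }
  stopifnot(length(background) == 4)
  if (is.null(names(background))) names(background) <- DNA_BASES
  background <- background[DNA_BASES]
  if (abs(sum(background) - 1) > 1e-6) {
    stop("background frequencies sum to ", sum(background), ", not 1")
  }
  w <- nrow(matrix)
  score_bits <- log2(sweep(sweep(matrix, 2, pseudocount * background, "+"),
                           2, background, "/"))
  score_int <- round(score_bits / eps)
  structure(list(name = name %||% "motif", width = w, matrix = matrix,
                 background = background, pseudocount = pseudocount,
                 eps = eps, score_int = score_int),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model '", x$name, "': width ", x$width, ">\n", sep = "")
  invisible(x)
}

#' Consensus word of a motif (most probable letter per position)
#' @param model A [motif_model].
#' @return Character scalar of length `width`.
#' @export
motif_consensus <- function(model) {
  paste(DNA_BASES[apply(model$matrix, 1, which.max)], collapse = "")
}

# Exact distribution of the discretised word score under the iid background:
# returns list(min_int, probs) where probs[k] = P(total == min_int + k - 1).
pwm_score_distribution <- function(model) {
  si <- model$score_int
  bg <- model$background
  lo <- sum(apply(si, 1, min)); hi <- sum(apply(si, 1, max))
  probs <- numeric(hi - lo + 1)
  # running distribution over offsets relative to running minimum
  run_lo <- 0
  run <- 1
  for (i in seq_len(model$width)) {
    row <- si[i, ]
    new_lo <- run_lo + min(row)
    new_hi <- run_lo + length(run) - 1 + max(row)
    new <- numeric(new_hi - new_lo + 1)
    for (x in 1:4) {
      off <- run_lo + row[x] - new_lo
      idx <- seq_along(run) + off
      new[idx] <- new[idx] + run * bg[x]
    }
    run <- new
    run_lo <- new_lo
  }
  list(min_int = run_lo, probs = run)
}

# Survival function lookup table: sf[k] = P(total >= min_int + k - 1).
pwm_survival <- function(model) {
  d <- pwm_score_distribution(model)
  list(min_int = d$min_int, sf = rev(cumsum(rev(d$probs))))
}

#' Exact p-value of a PWM score
#'
#' `P(word score >= score)` for an iid background word, computed from the
#' exact DP distribution of the discretised score. Monotone non-increasing in
#' `score`.
#'
#' @param model A [motif_model].
#' @param score Log-odds score in bits (vectorised).
#' @return Numeric p-values in `[0, 1]`.
#' @export
pwm_pvalue <- function(model, score) {
  sv <- pwm_survival(model)
  idx <- round(score / model$eps) - sv$min_int + 1
  p <- numeric(length(idx))
  p[idx <= 0] <- 1
  inside <- idx >= 1 & idx <= length(sv$sf)
  p[inside] <- sv$sf[idx[inside]]
  p[idx > length(sv$sf)] <- 0
  p
}

# Smallest integer score whose p-value is <= p_threshold, plus the survival
# table (for annotating hits with their p-values).
pwm_threshold <- function(model, p_threshold) {
  sv <- pwm_survival(model)
  ok <- which(sv$sf <= p_threshold)
  thr <- if (length(ok)) sv$min_int + ok[1] - 1 else Inf
  list(min_score_int = thr, survival = sv)
}

#' Scan sequences with a PWM at a p-value threshold
#'
#' Both strands are scanned; a hit is reported wherever the window's score
#' p-value is at or below `p_threshold`. Positions are 0-based starts on the
#' forward strand. Overlapping hits are counted individually and a site may be
#' reported on both strands (FIMO semantics). Windows containing `N` never
#' match.
#'
#' @param seqs Named character vector of DNA sequences, or a tibble with
#'   columns `id` and `seq`.
#' @param model A [motif_model].
#' @param p_threshold Hit p-value threshold (default `1e-4`).
#' @return Tibble with columns `seq_id`, `position`, `strand`, `score`
#'   (bits), `p_value`.
#' @export
scan_motif <- function(seqs, model, p_threshold = 1e-4) {
  if (is.data.frame(seqs)) {
    seq_vec <- setNames(seqs$seq, seqs$id)
  } else {
    seq_vec <- seqs
    if (is.null(names(seq_vec))) names(seq_vec) <- paste0("seq", seq_along(seq_vec))
  }
  thr <- pwm_threshold(model, p_threshold)
  out <- purrr::imap(seq_vec, function(s, id) {
    bind_rows(
      scan_one_strand(s, model, thr, "+", id),
      scan_one_strand(revcomp(s), model, thr, "-", id, forward_len = nchar(s))
    )
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(seq_id = character(), position = integer(),
                  strand = character(), score = numeric(), p_value = numeric()))
  }
  arrange(res, .data$seq_id, .data$position, .data$strand)
}

scan_one_strand <- function(s, model, thr, strand, id, forward_len = NULL) {
  w <- model$width
  n <- nchar(s)
  if (n < w) return(NULL)
  code <- match(seq_chars(s), DNA_BASES)
  n_win <- n - w + 1L
  total <- numeric(n_win)
  valid <- rep(TRUE, n_win)
  for (i in seq_len(w)) {
    ci <- code[i:(i + n_win - 1L)]
    na <- is.na(ci)
    valid <- valid & !na
    ci[na] <- 1L
    total <- total + model$score_int[i, ci]
  }
  hit <- which(valid & total >= thr$min_score_int)
  if (length(hit) == 0) return(NULL)
  pos0 <- hit - 1L
  if (strand == "-") pos0 <- forward_len - (hit - 1L) - w
  sv <- thr$survival
  idx <- pmin(pmax(total[hit] - sv$min_int + 1, 1), length(sv$sf))
  tibble(seq_id = id, position = as.integer(pos0), strand = strand,
         score = total[hit] * model$eps, p_value = sv$sf[idx])
}

#' Motif occurrence-rate enrichment between two sequence pools
#'
#' Tests whether motif hits are disproportionate to base-pair exposure: under
#' the null, expected hits in each pool are proportional to the pool's total
#' bp. `chi2 = sum (obs - exp)^2 / exp` with 1 degree of freedom; the p-value
#' is the chi-squared survival function. The per-pool rate is reported in the
#' "one hit every X bp" form (bp/hits, rounded to an integer).
#'
#' @param hits_fg,hits_bg Hit counts in the foreground/background pools.
#' @param bp_fg,bp_bg Total base pairs scanned in each pool.
#' @return Object of class `motif_enrichment`.
#' @export
motif_enrichment <- function(hits_fg, bp_fg, hits_bg, bp_bg) {
  stopifnot(hits_fg >= 0, hits_bg >= 0, bp_fg > 0, bp_bg > 0)
  total <- hits_fg + hits_bg
  exp_fg <- total * bp_fg / (bp_fg + bp_bg)
  exp_bg <- total * bp_bg / (bp_fg + bp_bg)
  chi2 <- if (total == 0) 0 else
    (hits_fg - exp_fg)^2 / exp_fg + (hits_bg - exp_bg)^2 / exp_bg
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(hits_fg = hits_fg, hits_bg = hits_bg,
                 bp_fg = bp_fg, bp_bg = bp_bg,
                 rate_fg = if (hits_fg > 0) bp_fg / hits_fg else NA_real_,
                 rate_bg = if (hits_bg > 0) bp_bg / hits_bg else NA_real_,
                 chi2 = chi2, p_value = p),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  fmt_rate <- function(r) if (is.na(r)) "no hits" else
    sprintf("once every %d bp", round(r))
  cat("Motif occurrence-rate enrichment (hits counted on both strands)\n")
  cat(sprintf("  foreground: %d hits / %d bp (%s)\n",
              x$hits_fg, x$bp_fg, fmt_rate(x$rate_fg)))
  cat(sprintf("  background: %d hits / %d bp (%s)\n",
              x$hits_bg, x$bp_bg, fmt_rate(x$rate_bg)))
  cat(sprintf("  chi-squared = %.3f (1 df), p = %.4g\n", x$chi2, x$p_value))
  invisible(x)
}
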