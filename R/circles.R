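#' Circle-scan configuration
#'
#' Parameters of the circular-contig classifier and the long-circle length
#' analysis. A contig is "circular" when its longest exact terminal direct
#' repeat (a prefix that is also a suffix, the two copies non-overlapping) is
#' at least `k_repeat` nucleotides -- the k-mer signature that De Bruijn
#' assemblers leave on contigs assembled from circular molecules.
#'
#' @param k_repeat Minimum terminal-repeat length in bp (default 77, the
#'   largest assembly k-mer).
#' @param pool_cutoff Trimmed-length boundary between the "short" and "long"
#'   circle pools (default 500 bp; short is strictly below).
#' @param spacing_window Length window (bp) over which inter-peak spacing of
#'   the long-circle length distribution is estimated.
#' @param kde_bandwidth Gaussian kernel bandwidth in bp.
#' @param grid_step KDE evaluation grid step in bp.
#' @param peak_prominence_fraction Minimum peak prominence as a fraction of
#'   the global density maximum.
#' @param dust_window,dust_level Window size and score threshold of the DUST
#'   low-complexity mask.
#' @return A list of class `circle_scan_config`.
#' @export
circle_scan_config <- function(k_repeat = 77, pool_cutoff = 500,
                               spacing_window = c(600, 800),
                               kde_bandwidth = 1.0, grid_step = 0.25,
                               peak_prominence_fraction = 0.10,
                               dust_window = 64, dust_level = 2.0) {
  stopifnot(k_repeat >= 1, pool_cutoff > 0,
            length(spacing_window) == 2, spacing_window[1] < spacing_window[2])
  structure(list(k_repeat = as.integer(k_repeat),
                 pool_cutoff = as.integer(pool_cutoff),
                 spacing_window = spacing_window,
                 kde_bandwidth = kde_bandwidth, grid_step = grid_step,
                 peak_prominence_fraction = peak_prominence_fraction,
                 dust_window = as.integer(dust_window),
                 dust_level = dust_level),
            class = "circle_scan_config")
}

# Longest k in [k_min, floor(n/2)] with prefix(k) == suffix(k); 0 if none.
# Candidate k values are pre-filtered on the first character so most linear
# contigs are dismissed after a handful of substring comparisons.
longest_terminal_repeat <- function(seq, k_min) {
  n <- nchar(seq)
  k_max <- n %/% 2L
  if (k_max < k_min) return(0L)
  first <- substr(seq, 1L, 1L)
  starts <- n - (k_min:k_max) + 1L
  cand <- (k_min:k_max)[substring(seq, starts, starts) == first]
  for (k in rev(cand)) {
    if (substr(seq, 1L, k) == substr(seq, n - k + 1L, n)) return(k)
  }
  0L
}

#' Classify contigs as circular by their terminal direct repeats
#'
#' A contig is labelled circular iff the longest exact prefix that is also a
#' suffix (the two copies not overlapping) has length `>= k_repeat`. Circular
#' contigs get a `trimmed_seq` with exactly `k_repeat` bases removed from the
#' 3' end, mirroring assemblers' removal of the duplicated terminal k-mer;
#' linear contigs are untouched. Contigs shorter than `2 * k_repeat` cannot be
#' circular and are classified linear.
#'
#' @param contigs Tibble with columns `id` and `seq` (e.g. from [read_fasta]).
#' @param config A [circle_scan_config].
#' @return The input tibble with added columns `border_length`, `is_circular`,
#'   `trimmed_seq` and `trimmed_length`.
#' @export
detect_circles <- function(contigs, config = circle_scan_config()) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  k <- config$k_repeat
  border <- vapply(contigs$seq, longest_terminal_repeat, integer(1),
                   k_min = k, USE.NAMES = FALSE)
  circ <- border >= k
  trimmed <- ifelse(circ,
                    substr(contigs$seq, 1L, nchar(contigs$seq) - k),
                    contigs$seq)
  contigs |>
    mutate(border_length = border,
           is_circular = circ,
           trimmed_seq = trimmed,
           trimmed_length = nchar(trimmed))
}

#' Split classified circles into short and long pools
#'
#' Circles with trimmed length strictly below `pool_cutoff` form the short
#' pool; the rest the long pool. Summary statistics (count, median length,
#' coverage quartiles) are reported per pool; an empty pool is flagged with
#' `NA` statistics.
#'
#' @param circles Tibble of circular contigs (rows with `is_circular == TRUE`
#'   are used if the column is present).
#' @param config A [circle_scan_config].
#' @return List with elements `short`, `long` (tibbles) and `summary`.
#' @export
split_pools <- function(circles, config = circle_scan_config()) {
  if ("is_circular" %in% names(circles)) {
    circles <- filter(circles, .data$is_circular)
  }
  len <- if ("trimmed_length" %in% names(circles)) circles$trimmed_length else circles$length
  short <- circles[len < config$pool_cutoff, , drop = FALSE]
  long <- circles[len >= config$pool_cutoff, , drop = FALSE]
  pool_stats <- function(tbl, label) {
    l <- if ("trimmed_length" %in% names(tbl)) tbl$trimmed_length else tbl$length
    cv <- if ("coverage" %in% names(tbl)) tbl$coverage else rep(NA_real_, nrow(tbl))
    tibble(pool = label, n = nrow(tbl),
           median_length = if (nrow(tbl)) stats::median(l) else NA_real_,
           coverage_q25 = if (nrow(tbl) && any(!is.na(cv))) stats::quantile(cv, .25, na.rm = TRUE) else NA_real_,
           coverage_median = if (nrow(tbl) && any(!is.na(cv))) stats::median(cv, na.rm = TRUE) else NA_real_,
           coverage_q75 = if (nrow(tbl) && any(!is.na(cv))) stats::quantile(cv, .75, na.rm = TRUE) else NA_real_)
  }
  list(short = as_tibble(short), long = as_tibble(long),
       summary = bind_rows(pool_stats(short, "short"), pool_stats(long, "long")))
}

# Per-base DUST mask of one sequence. Windows of `window` bases slide by one;
# a window whose triplet score S = sum n_t (n_t - 1) / 2 / (w_triplets - 1)
# exceeds `level` is masked whole. Triplets containing N are not counted.
dust_mask <- function(seq, window = 64, level = 2.0) {
  n <- nchar(seq)
  if (n < 3) return(rep(FALSE, n))
  chars <- seq_chars(seq)
  code <- match(chars, DNA_BASES)          # NA for N
  t1 <- code[1:(n - 2)]; t2 <- code[2:(n - 1)]; t3 <- code[3:n]
  tri <- (t1 - 1L) * 16L + (t2 - 1L) * 4L + t3   # 1..64, NA if any N
  w <- min(window, n)
  n_tri_w <- w - 2L
  counts <- integer(64)
  masked <- rep(FALSE, n)
  n_win <- n - w + 1L
  # initial window
  for (t in tri[seq_len(n_tri_w)]) if (!is.na(t)) counts[t] <- counts[t] + 1L
  score <- sum(counts * (counts - 1L)) / 2 / (n_tri_w - 1L)
  if (score > level) masked[1:w] <- TRUE
  if (n_win > 1L) {
    for (s in 2:n_win) {
      out_t <- tri[s - 1L]
      in_t <- tri[s + n_tri_w - 1L]
      if (!is.na(out_t)) {
        counts[out_t] <- counts[out_t] - 1L
        score <- score - (counts[out_t]) / (n_tri_w - 1L)
      }
      if (!is.na(in_t)) {
        score <- score + (counts[in_t]) / (n_tri_w - 1L)
        counts[in_t] <- counts[in_t] + 1L
      }
      if (score > level) masked[s:(s + w - 1L)] <- TRUE
    }
  }
  masked
}

#' Fraction of a sequence masked as low complexity (DUST)
#'
#' Classic windowed DUST: within each sliding window the triplet score
#' `S = sum_t n_t (n_t - 1) / 2 / (w_triplets - 1)` is computed over the 64
#' trinucleotides; windows with `S > level` are masked and the masked fraction
#' of the sequence is returned. Vectorised over sequences.
#'
#' @param seq Character vector of DNA sequences.
#' @param window Window size in bp (default 64).
#' @param level Score threshold (default 2.0).
#' @return Numeric vector of masked-base fractions in `[0, 1]`.
#' @export
dust_fraction <- function(seq, window = 64, level = 2.0) {
  vapply(seq, function(s) {
    if (nchar(s) == 0) return(0)
    mean(dust_mask(s, window = window, level = level))
  }, numeric(1), USE.NAMES = FALSE)
}

# Peak prominence on a regular grid: height above the higher of the two
# valley floors separating the peak from higher terrain (or the series ends).
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- if (p > 1) {
      higher <- which(y[1:(p - 1)] > h)
      lo <- if (length(higher)) max(higher) + 1 else 1
      min(y[lo:(p - 1)])
    } else h
    right <- if (p < length(y)) {
      higher <- which(y[(p + 1):length(y)] > h)
      hi <- if (length(higher)) p + min(higher) - 1 else length(y)
      min(y[(p + 1):hi])
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Estimate inter-peak spacing of a length distribution
#'
#' Evaluates a Gaussian kernel density of the lengths over the configured
#' window, finds local maxima whose prominence is at least
#' `peak_prominence_fraction` of the global maximum, and reports the mean
#' spacing between successive peaks. An autocorrelation-based secondary
#' estimate (first off-origin peak of the autocovariance of 1-bp binned
#' counts) is returned for cross-checking.
#'
#' @param lengths Integer vector of (trimmed) circle lengths in bp.
#' @param config A [circle_scan_config].
#' @return Object of class `peak_spacing` with elements `spacing`, `peaks`,
#'   `n_peaks`, `acf_spacing`, `density` (tibble `x`, `y`) and `n`.
#'   `spacing` is `NA` (flagged) when fewer than two peaks are found.
#' @export
peak_spacing <- function(lengths, config = circle_scan_config()) {
  win <- config$spacing_window
  x <- lengths[lengths >= win[1] & lengths <= win[2]]
  if (length(x) < 200) {
    stop("peak_spacing needs at least 200 lengths within [",
         win[1], ", ", win[2], "]; got ", length(x))
  }
  grid_n <- round((win[2] - win[1]) / config$grid_step) + 1
  d <- stats::density(x, bw = config$kde_bandwidth, from = win[1], to = win[2],
                      n = grid_n)
  y <- d$y
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(cand)) {
    prom <- peak_prominences(y, cand)
    cand <- cand[prom >= config$peak_prominence_fraction * max(y)]
  }
  peaks <- d$x[cand]
  spacing <- if (length(peaks) >= 2) mean(diff(peaks)) else NA_real_

  # secondary: autocovariance of 1-bp binned counts
  bins <- tabulate(round(x) - win[1] + 1L, nbins = win[2] - win[1] + 1L)
  ac <- stats::acf(bins, lag.max = min(40, length(bins) - 1), plot = FALSE,
                   demean = TRUE)$acf[-1]
  ac_peaks <- which(diff(sign(diff(ac))) < 0) + 1L
  acf_spacing <- if (length(ac_peaks)) ac_peaks[which.max(ac[ac_peaks])] else NA_real_

  structure(list(spacing = spacing, peaks = peaks, n_peaks = length(peaks),
                 acf_spacing = as.numeric(acf_spacing),
                 density = tibble(x = d$x, y = y), n = length(x),
                 config = config),
            class = "peak_spacing")
}

#' @export
print.peak_spacing <- function(x, ...) {
  cat("Inter-peak spacing estimate\n")
  cat("  n lengths in window:", x$n, "\n")
  cat("  peaks found:", x$n_peaks, "\n")
  if (is.na(x$spacing)) {
    cat("  spacing: undefined (< 2 peaks)\n")
  } else {
    cat(sprintf("  mean KDE spacing: %.3f bp\n", x$spacing))
    cat(sprintf("  autocorrelation spacing: %.1f bp\n", x$acf_spacing))
  }
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of length distributions
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' CDFs. The p-value uses the asymptotic series
#' `Q(lambda) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2)` with
#' `lambda = (sqrt(n_e) + 0.12 + 0.11 / sqrt(n_e)) * D` and effective size
#' `n_e = n1 n2 / (n1 + n2)`, truncated once terms fall below `1e-12`.
#'
#' @param lengths_a,lengths_b Numeric samples.
#' @return Object of class `ks_compare` with fields `D`, `p_value`, `n1`, `n2`.
#' @export
ks_compare <- function(lengths_a, lengths_b) {
  a <- sort(lengths_a); b <- sort(lengths_b)
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 > 0, n2 > 0)
  pooled <- sort(unique(c(a, b)))
  ecdf_a <- findInterval(pooled, a) / n1
  ecdf_b <- findInterval(pooled, b) / n2
  D <- max(abs(ecdf_a - ecdf_b))
  ne <- n1 * n2 / (n1 + n2)
  lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  p <- ks_series(lam)
  structure(list(D = D, p_value = p, n1 = n1, n2 = n2), class = "ks_compare")
}

ks_series <- function(lambda) {
  if (lambda <= 0) return(1)
  total <- 0
  for (j in 1:1000) {
    term <- 2 * (-1)^(j - 1) * exp(-2 * j^2 * lambda^2)
    total <- total + term
    if (abs(term) < 1e-12) break
  }
  min(max(total, 0), 1)
}

#' @export
print.ks_compare <- function(x, ...) {
  cat(sprintf("Two-sample KS test: D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$D, x$p_value, x$n1, x$n2))
  invisible(x)
}
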