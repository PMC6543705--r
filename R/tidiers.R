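# broom-style tidiers for the package's result objects.

#' @export
tidy.ks_compare <- function(x, ...) {
  tibble(statistic = x$D, p.value = x$p_value, n1 = x$n1, n2 = x$n2,
         method = "two-sample Kolmogorov-Smirnov (asymptotic)")
}

#' @export
glance.ks_compare <- function(x, ...) tidy(x)

#' @export
tidy.motif_enrichment <- function(x, ...) {
  tibble(pool = c("foreground", "background"),
         hits = c(x$hits_fg, x$hits_bg),
         bp = c(x$bp_fg, x$bp_bg),
         bp_per_hit = c(x$rate_fg, x$rate_bg))
}

#' @export
glance.motif_enrichment <- function(x, ...) {
  tibble(statistic = x$chi2, df = 1, p.value = x$p_value,
         rate_ratio = (x$hits_fg / x$bp_fg) / (x$hits_bg / x$bp_bg))
}

#' @export
tidy.peak_spacing <- function(x, ...) {
  tibble(peak = seq_along(x$peaks), position = x$peaks)
}

#' @export
glance.peak_spacing <- function(x, ...) {
  tibble(spacing = x$spacing, n_peaks = x$n_peaks,
         acf_spacing = x$acf_spacing, n = x$n)
}

#' @export
tidy.circle_families <- function(x, ...) x$membership

#' @export
glance.circle_families <- function(x, ...) {
  tibble(n_families = x$n_families,
         n_circles = nrow(x$membership),
         neighbor_fraction = x$neighbor_fraction,
         largest_family = max(x$membership$family_size))
}

#' @export
tidy.cascade_report <- function(x, ...) {
  tibble(step = c("step1_prokaryote", "step2_host_besthit",
                  "step3_reciprocal", "retained"),
         n = c(length(x$removed_step1), length(x$removed_step2),
               length(x$removed_step3), length(x$retained)),
         ids = list(x$removed_step1, x$removed_step2, x$removed_step3,
                    x$retained))
}

#' @export
glance.cascade_report <- function(x, ...) {
  tibble(n_input = x$n_input,
         n_removed = x$n_input - length(x$retained),
         n_retained = length(x$retained))
}

#' @export
tidy.pair_map_report <- function(x, ...) {
  tibble(category = c("both_same_circle", "mate_low_complexity",
                      "mate_elsewhere"),
         n = c(x$both_same_circle, x$mate_low_complexity, x$mate_elsewhere))
}

#' @export
glance.pair_map_report <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_unanchored = x$n_unanchored,
         elsewhere_fraction = if (x$n_pairs > 0) x$mate_elsewhere / x$n_pairs else NA_real_,
         threshold = x$threshold,
         precursor_evidence = x$precursor_evidence)
}

#' @export
tidy.supermatrix <- function(x, ...) x$offsets

#' @export
glance.supermatrix <- function(x, ...) {
  tibble(n_taxa = x$n_taxa, total_positions = x$total_positions,
         missing_fraction = x$missing_fraction,
         n_partitions = nrow(x$offsets))
}

#' @export
tidy.q_selection <- function(x, ...) x$report

#' @export
glance.q_selection <- function(x, ...) {
  tibble(n_partitions = nrow(x$report), n_selected = x$n_selected,
         selected_positions = x$selected_positions,
         q_cut = x$q_cut, min_fraction = x$min_fraction)
}

#' @export
tidy.composition_profile <- function(x, ...) {
  as_tibble(x$f, rownames = "taxon") |>
    tidyr::pivot_longer(-"taxon", names_to = "state", values_to = "frequency")
}

#' @export
glance.composition_profile <- function(x, ...) {
  tibble(rcfv = x$rcfv, n_taxa = nrow(x$f),
         n_all_missing = length(x$all_missing))
}
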