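#' Decontamination cascade configuration
#'
#' Identity thresholds of the three filtering steps. Their strictness follows
#' the cascade's definition exactly: step 1 removes at `>= prok_min_identity`,
#' step 2 strictly above `host_min_identity_step2`, step 3 at
#' `>= host_min_identity_step3`. Identity is
#' `100 * identical positions / aligned columns` with gaps in the
#' denominator.
#'
#' @param prok_min_identity Step-1 threshold (default 50).
#' @param host_min_identity_step2 Step-2 threshold (default 70, strict).
#' @param host_min_identity_step3 Step-3 threshold (default 80).
#' @param scheme Protein [scoring_scheme] used for all alignments.
#' @return List of class `cascade_config`.
#' @export
cascade_config <- function(prok_min_identity = 50,
                           host_min_identity_step2 = 70,
                           host_min_identity_step3 = 80,
                           scheme = protein_scheme()) {
  stopifnot(prok_min_identity >= 0, prok_min_identity <= 100,
            host_min_identity_step2 >= 0, host_min_identity_step2 <= 100,
            host_min_identity_step3 >= 0, host_min_identity_step3 <= 100)
  structure(list(prok_min_identity = prok_min_identity,
                 host_min_identity_step2 = host_min_identity_step2,
                 host_min_identity_step3 = host_min_identity_step3,
                 scheme = scheme),
            class = "cascade_config")
}

# Best hit of every query against one database: vectorised score pass, then a
# full alignment of score ties to resolve identity. Ties broken by higher
# identity, then lexicographic subject id.
best_hits <- function(queries, db, scheme) {
  if (nrow(db) == 0 || nrow(queries) == 0) {
    return(tibble(query_id = queries$id, subject_id = NA_character_,
                  score = -Inf, identity = NA_real_))
  }
  scores <- matrix(NA_real_, nrow(queries), nrow(db))
  for (j in seq_len(nrow(db))) {
    scores[, j] <- align_scores_vs_subject(queries$seq, db$seq[j], scheme)
  }
  purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    smax <- max(scores[i, ])
    cand <- which(scores[i, ] == smax)
    recs <- purrr::map_dfr(cand, function(j) {
      h <- align_local(queries$seq[i], db$seq[j], scheme,
                       query_id = queries$id[i], subject_id = db$id[j])
      h[, c("subject_id", "score", "identity")]
    })
    recs <- arrange(recs, dplyr::desc(.data$identity), .data$subject_id)
    tibble(query_id = queries$id[i], subject_id = recs$subject_id[1],
           score = smax, identity = recs$identity[1])
  })
}

# Best hit of each query over several labelled databases.
best_hits_all <- function(queries, dbs, scheme) {
  per_db <- purrr::imap(dbs, function(db, label) {
    mutate(best_hits(queries, db, scheme), db = label)
  })
  bind_rows(per_db) |>
    group_by(.data$query_id) |>
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$identity),
            .data$subject_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
}

#' Step 1: remove queries whose overall best hit is prokaryotic
#'
#' A query is removed iff its best-scoring hit across all reference databases
#' is in the prokaryote set and that hit's identity is at least
#' `prok_min_identity`.
#'
#' @param queries Tibble (`id`, `seq`).
#' @param prok_db,host_db,other_db Reference tibbles (`id`, `seq`).
#' @param config A [cascade_config].
#' @return Character vector of removed query ids.
#' @export
step1_prokaryote <- function(queries, prok_db, host_db, other_db,
                             config = cascade_config()) {
  if (nrow(queries) == 0) return(character(0))
  best <- best_hits_all(queries,
                        list(prok = prok_db, host = host_db, other = other_db),
                        config$scheme)
  removed <- filter(best, .data$db == "prok",
                    .data$identity >= config$prok_min_identity)
  removed$query_id
}

#' Step 2: remove queries whose best hit is the host, by score margin
#'
#' A query is removed iff its best local-alignment score against the host
#' database strictly exceeds its best score against every other reference
#' database AND the host hit's identity strictly exceeds
#' `host_min_identity_step2`.
#'
#' @inheritParams step1_prokaryote
#' @return Character vector of removed query ids.
#' @export
step2_host_besthit <- function(queries, host_db, prok_db, other_db,
                               config = cascade_config()) {
  if (nrow(queries) == 0 || nrow(host_db) == 0) return(character(0))
  host_best <- best_hits(queries, host_db, config$scheme)
  nonhost <- bind_rows(best_hits(queries, prok_db, config$scheme),
                       best_hits(queries, other_db, config$scheme)) |>
    group_by(.data$query_id) |>
    summarise(best_nonhost = max(.data$score), .groups = "drop")
  joined <- dplyr::left_join(host_best, nonhost, by = "query_id")
  joined$best_nonhost[is.na(joined$best_nonhost)] <- -Inf
  removed <- filter(joined, .data$score > .data$best_nonhost,
                    .data$identity > config$host_min_identity_step2)
  removed$query_id
}

#' Step 3: reciprocal capture by host queries
#'
#' Each host protein is queried against the combined database of the other
#' metazoan references plus the surviving candidate set; a candidate is
#' removed iff it is some host query's best hit with identity at least
#' `host_min_identity_step3`.
#'
#' @param host_queries Tibble (`id`, `seq`) of host proteins.
#' @param candidates Tibble (`id`, `seq`) of surviving parasite candidates.
#' @param other_db Tibble (`id`, `seq`) of non-host metazoan references.
#' @param config A [cascade_config].
#' @return Character vector of removed candidate ids.
#' @export
step3_reciprocal <- function(host_queries, candidates, other_db,
                             config = cascade_config()) {
  if (nrow(host_queries) == 0 || nrow(candidates) == 0) return(character(0))
  best <- best_hits_all(host_queries,
                        list(candidate = candidates, other = other_db),
                        config$scheme)
  captured <- filter(best, .data$db == "candidate",
                     .data$identity >= config$host_min_identity_step3)
  unique(captured$subject_id)
}

#' Run the three-step decontamination cascade
#'
#' Steps are applied in order, each to the survivors of the previous one;
#' the removed sets and the retained set partition the input ids.
#'
#' @param queries Tibble (`id`, `seq`) of candidate parasite proteins.
#' @param host_db,prok_db,other_db Reference tibbles (`id`, `seq`).
#' @param config A [cascade_config].
#' @return Object of class `cascade_report` with id sets `removed_step1`,
#'   `removed_step2`, `removed_step3`, `retained`.
#' @export
run_cascade <- function(queries, host_db, prok_db, other_db,
                        config = cascade_config()) {
  r1 <- step1_prokaryote(queries, prok_db, host_db, other_db, config)
  surv1 <- filter(queries, !.data$id %in% r1)
  r2 <- step2_host_besthit(surv1, host_db, prok_db, other_db, config)
  surv2 <- filter(surv1, !.data$id %in% r2)
  r3 <- step3_reciprocal(host_db, surv2, other_db, config)
  retained <- setdiff(surv2$id, r3)
  structure(list(removed_step1 = r1, removed_step2 = r2, removed_step3 = r3,
                 retained = retained, n_input = nrow(queries),
                 config = config),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Decontamination cascade:", x$n_input, "input proteins\n")
  cat("  step 1 (prokaryote best hit):", length(x$removed_step1), "removed\n")
  cat("  step 2 (host best hit):      ", length(x$removed_step2), "removed\n")
  cat("  step 3 (reciprocal capture): ", length(x$removed_step3), "removed\n")
  cat("  retained:", length(x$retained), "\n")
  invisible(x)
}
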