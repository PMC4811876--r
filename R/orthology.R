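#' Orthology thresholds
#'
#' Gates applied to all-vs-all local alignments before best-match selection:
#' hits are retained when the expectation value is strictly below
#' `max_evalue` and the identity fraction strictly above `min_identity`
#' (both read literally as strict inequalities, so identity exactly 0.40 is
#' rejected at the default gate).
#'
#' @param max_evalue Maximum expectation value (exclusive), default 1e-20.
#' @param min_identity Minimum identity fraction (exclusive), default 0.40.
#' @return A list of class `orthology_thresholds`.
#' @export
orthology_thresholds <- function(max_evalue = 1e-20, min_identity = 0.40) {
  if (max_evalue <= 0) abort("max_evalue must be positive")
  if (min_identity < 0 || min_identity > 1) abort("min_identity must be in [0, 1]")
  structure(list(max_evalue = max_evalue, min_identity = min_identity),
            class = "orthology_thresholds")
}

#' Filter alignment hits by the retention gates
#'
#' @param hits A tibble of [align_local()] rows.
#' @param thresholds An [orthology_thresholds()] object.
#' @return The retained subset of `hits`.
#' @export
filter_retained <- function(hits, thresholds = orthology_thresholds()) {
  hits |>
    dplyr::filter(.data$evalue < thresholds$max_evalue,
                  !is.nan(.data$identity),
                  .data$identity > thresholds$min_identity)
}

#' All-vs-all retained hits between two genomes
#'
#' Aligns every query against every target and keeps the hits that pass the
#' retention gates. Expectation values use the total residue count of the
#' target set as the database size.
#'
#' @param queries,targets Non-empty [protein_records] tibbles.
#' @param thresholds An [orthology_thresholds()] object.
#' @param params An [alignment_params()] object.
#' @return A tibble of retained hits.
#' @export
retained_hits <- function(queries, targets,
                          thresholds = orthology_thresholds(),
                          params = alignment_params()) {
  if (nrow(queries) == 0L || nrow(targets) == 0L) {
    abort("retained_hits requires non-empty query and target genomes")
  }
  filter_retained(align_all(queries, targets, params), thresholds)
}

#' Best retained match per query
#'
#' The best match is the retained hit with the highest raw score; ties are
#' broken by lower expectation value, then lexicographically smaller target
#' ID, so the choice is deterministic.
#'
#' @param hits A tibble of retained hits.
#' @return One row per `query_id` (queries without hits are absent).
#' @export
best_match <- function(hits) {
  hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(dplyr::desc(.data$raw_score), .data$evalue, .data$target_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

#' Reciprocal-best-hit orthology classification
#'
#' Classifies every query gene against a target genome into the three-way
#' scheme of cross-genome family comparisons: `one_to_one` when gene A's best
#' retained match B also has A as its best retained match in the reverse
#' direction; `homolog_no_ortholog` when A has retained hits but the best
#' match is not reciprocal; `absent` when no hit passes the gates.
#' Classification is cross-genome only; self-comparison within a genome is
#' never performed.
#'
#' @param query_genome,target_genome [protein_records] tibbles; IDs must be
#'   unique within each genome.
#' @param thresholds An [orthology_thresholds()] object.
#' @param params An [alignment_params()] object.
#' @param target_label Genome label recorded in the output; defaults to the
#'   `genome` field of `target_genome` when present.
#' @return A tibble with one row per query gene: `query_id`,
#'   `target_genome`, `category`, `best_target_id`, `reciprocal`.
#' @export
classify_orthologs <- function(query_genome, target_genome,
                               thresholds = orthology_thresholds(),
                               params = alignment_params(),
                               target_label = NULL) {
  if (anyDuplicated(query_genome$id) || anyDuplicated(target_genome$id)) {
    abort("duplicate protein IDs within a genome")
  }
  if (is.null(target_label)) {
    target_label <- if ("genome" %in% names(target_genome) &&
                        !is.na(target_genome$genome[1L])) {
      target_genome$genome[1L]
    } else "target"
  }
  hits_qt <- align_all(query_genome, target_genome, params)
  # reverse-direction hits reuse the same alignments: score and identity are
  # symmetric, only the expectation value changes with query length and
  # database size
  hits_tq <- hits_qt |>
    dplyr::mutate(
      evalue = evalue_ka(.data$raw_score, nchar(target_genome$sequence)[
        match(.data$target_id, target_genome$id)],
        sum(nchar(query_genome$sequence)), params)
    ) |>
    dplyr::rename(query_id = "target_id", target_id = "query_id")
  best_qt <- best_match(filter_retained(hits_qt, thresholds))
  best_tq <- best_match(filter_retained(hits_tq, thresholds))
  fwd <- setNames(best_qt$target_id, best_qt$query_id)
  rev <- setNames(best_tq$target_id, best_tq$query_id)
  purrr::map_dfr(query_genome$id, function(q) {
    b <- unname(fwd[q])
    if (is.na(b)) {
      tibble::tibble(query_id = q, target_genome = target_label,
                     category = "absent", best_target_id = NA_character_,
                     reciprocal = FALSE)
    } else {
      recip <- !is.na(rev[b]) && unname(rev[b]) == q
      tibble::tibble(query_id = q, target_genome = target_label,
                     category = if (recip) "one_to_one" else "homolog_no_ortholog",
                     best_target_id = b, reciprocal = recip)
    }
  })
}

#' Orthology matrix across several target genomes
#'
#' @param query_genome A [protein_records] tibble.
#' @param target_genomes Named list of [protein_records] tibbles.
#' @inheritParams classify_orthologs
#' @return A tibble of [classify_orthologs()] rows over all target genomes.
#' @export
orthology_matrix <- function(query_genome, target_genomes,
                             thresholds = orthology_thresholds(),
                             params = alignment_params()) {
  purrr::imap_dfr(target_genomes, function(tg, label) {
    classify_orthologs(query_genome, tg, thresholds, params, target_label = label)
  })
}
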