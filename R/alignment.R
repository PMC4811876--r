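#' Alignment parameters
#'
#' Parameters for exact affine-gap local alignment and its Karlin-Altschul
#' expectation statistics. Defaults follow standard protein-search practice:
#' BLOSUM62 with gap open 11 and gap extend 1 (a gap of length L costs
#' `gap_open + L * gap_extend`), and the gapped Karlin-Altschul constants
#' lambda = 0.267, kappa = 0.041 for that scoring system. Exact
#' Smith-Waterman with these parameters is a conservative stand-in for
#' heuristic protein search: it never misses the optimal local alignment.
#'
#' @param substitution_matrix Named square integer score matrix; default
#'   BLOSUM62 (see [default_substitution_matrix()]).
#' @param gap_open Positive gap-opening penalty.
#' @param gap_extend Positive per-residue gap-extension penalty; must not
#'   exceed `gap_open`.
#' @param lambda,kappa Positive Karlin-Altschul scale and prefactor.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = NULL, gap_open = 11,
                             gap_extend = 1, lambda = 0.267, kappa = 0.041) {
  if (is.null(substitution_matrix)) {
    substitution_matrix <- default_substitution_matrix()
  }
  stopifnot(is.matrix(substitution_matrix),
            nrow(substitution_matrix) == ncol(substitution_matrix),
            !is.null(rownames(substitution_matrix)))
  if (gap_extend > gap_open) abort("gap_extend must not exceed gap_open")
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be positive")
  if (lambda <= 0 || kappa <= 0) abort("lambda and kappa must be positive")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, kappa = kappa),
            class = "alignment_params")
}

#' Default substitution matrix (BLOSUM62)
#'
#' @return The BLOSUM62 score matrix with an `X` row/column.
#' @export
default_substitution_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Read a score matrix in NCBI text format
#'
#' Parses the standard whitespace-separated matrix layout (comment lines
#' starting with `#`, a header row of residue letters, one labeled row per
#' residue).
#'
#' @param path Path to the matrix file.
#' @return A named integer matrix.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labels <- vapply(rows, `[[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  vals
}

encode_sequence <- function(sequence, alphabet) {
  chars <- strsplit(sequence, "")[[1L]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    x <- match("X", alphabet)
    if (is.na(x)) abort("sequence contains letters outside the score matrix alphabet")
    idx[is.na(idx)] <- x
  }
  idx
}

#' Local pairwise protein alignment
#'
#' Optimal Smith-Waterman local alignment under affine gap penalties, with a
#' deterministic traceback (ties resolved diagonal, then up, then left).
#' Identity is counted over all aligned columns, gap columns included in the
#' denominator. When every attainable column score is negative the optimal
#' local alignment is empty: score 0, identity `NaN`, empty span.
#'
#' @param a,b Protein sequences as character strings, or single-row
#'   [protein_records] tibbles.
#' @param params An [alignment_params()] object.
#' @param query_id,target_id IDs recorded in the output (taken from tibble
#'   input when present).
#' @param db_residues Database size (residues) used for the expectation
#'   value; defaults to `nchar(b)`.
#' @return A one-row tibble: `query_id`, `target_id`, `raw_score`, `evalue`,
#'   `identity`, `n_columns`, `n_matches`, and the 1-based inclusive aligned
#'   span (`q_start`, `q_end`, `t_start`, `t_end`; zeros for an empty
#'   alignment).
#' @export
#' @examples
#' align_local("MKRDELLAALGYKV", "MKRDELLAALGYKV")
align_local <- function(a, b, params = alignment_params(),
                        query_id = "query", target_id = "target",
                        db_residues = NULL) {
  if (is.data.frame(a)) { query_id <- a$id[1L]; a <- a$sequence[1L] }
  if (is.data.frame(b)) { target_id <- b$id[1L]; b <- b$sequence[1L] }
  if (!nzchar(a) || !nzchar(b)) abort("cannot align an empty sequence")
  S <- params$substitution_matrix
  alphabet <- rownames(S)
  res <- cpp_align_local(encode_sequence(a, alphabet), encode_sequence(b, alphabet),
                         S, params$gap_open, params$gap_extend)
  ai <- res$a_idx
  bi <- res$b_idx
  n_col <- length(ai)
  n_match <- if (n_col == 0L) 0L else {
    both <- ai > 0L & bi > 0L
    sum(substring(a, ai[both], ai[both]) == substring(b, bi[both], bi[both]))
  }
  if (is.null(db_residues)) db_residues <- nchar(b)
  tibble::tibble(
    query_id = query_id, target_id = target_id,
    raw_score = res$score,
    evalue = evalue_ka(res$score, nchar(a), db_residues, params),
    identity = if (n_col > 0L) n_match / n_col else NaN,
    n_columns = n_col, n_matches = as.integer(n_match),
    q_start = if (n_col > 0L) min(ai[ai > 0L]) else 0L,
    q_end = if (n_col > 0L) max(ai) else 0L,
    t_start = if (n_col > 0L) min(bi[bi > 0L]) else 0L,
    t_end = if (n_col > 0L) max(bi) else 0L
  )
}

#' All-vs-all local alignments between two protein sets
#'
#' @param queries,targets [protein_records] tibbles.
#' @param params An [alignment_params()] object.
#' @param db_residues Database size used for expectation values; defaults to
#'   the total residue count of `targets`.
#' @return A tibble of [align_local()] rows, one per (query, target) pair.
#' @export
align_all <- function(queries, targets, params = alignment_params(),
                      db_residues = NULL) {
  if (is.null(db_residues)) db_residues <- sum(nchar(targets$sequence))
  purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    purrr::map_dfr(seq_len(nrow(targets)), function(j) {
      align_local(queries$sequence[i], targets$sequence[j], params,
                  query_id = queries$id[i], target_id = targets$id[j],
                  db_residues = db_residues)
    })
  })
}

#' Local-alignment score matrix for many pairs
#'
#' Optimal Smith-Waterman scores (same scoring system and recurrences as
#' [align_local()]) for every query-target pair at once, without traceback.
#' Useful for guide trees and exhaustive score checks.
#'
#' @param queries,targets Character vectors of sequences or
#'   [protein_records] tibbles.
#' @param params An [alignment_params()] object.
#' @return A numeric matrix of raw scores, queries in rows.
#' @export
align_score_matrix <- function(queries, targets, params = alignment_params()) {
  if (is.data.frame(queries)) queries <- setNames(queries$sequence, queries$id)
  if (is.data.frame(targets)) targets <- setNames(targets$sequence, targets$id)
  if (any(!nzchar(queries)) || any(!nzchar(targets))) {
    abort("cannot align an empty sequence")
  }
  S <- params$substitution_matrix
  alphabet <- rownames(S)
  out <- cpp_align_score_block(lapply(queries, encode_sequence, alphabet = alphabet),
                               lapply(targets, encode_sequence, alphabet = alphabet),
                               S, params$gap_open, params$gap_extend)
  dimnames(out) <- list(names(queries), names(targets))
  out
}

#' Karlin-Altschul expectation value
#'
#' `E = kappa * m * n * exp(-lambda * S)` for a local alignment of score `S`
#' between a query of `m` residues and a database of `n` residues: strictly
#' decreasing in the score and linear in both sizes.
#'
#' @param score Non-negative alignment raw score.
#' @param query_len Query length in residues (> 0).
#' @param db_residues Database size in residues (> 0).
#' @param params An [alignment_params()] object supplying lambda and kappa.
#' @return The expectation value.
#' @export
evalue_ka <- function(score, query_len, db_residues, params = alignment_params()) {
  if (any(query_len <= 0) || any(db_residues <= 0)) {
    abort("query_len and db_residues must be positive")
  }
  params$kappa * query_len * db_residues * exp(-params$lambda * score)
}
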