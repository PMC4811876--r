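#' Motif patterns and the bundled catalog
#'
#' Motif patterns are strings over amino-acid letters where `X` and `+` are
#' single-position wildcards and `[LIVF]` denotes a per-position alternative
#' set. The bundled catalog (`grasfam_example("gras_motif_catalog.tsv")`)
#' encodes the five core GRAS-domain motifs in their canonical order LHRI,
#' VHIID, LHRII, PFYRE, SAW, together with the N-terminal DELLA and TVHYNP
#' units of DELLA proteins, the LXXLL and `[LIVF]RITG` patterns, the RVER
#' unit absent from HAM-subfamily members, and the XIV/XV/XVI consensus
#' units. Match scores are the fraction of non-wildcard positions matched.
#'
#' @name motif_patterns
NULL

#' Read a motif catalog
#'
#' One motif per line: `name<TAB>region<TAB>pattern`, `#` comments allowed.
#' Region is `N_terminal` or `GRAS_domain`.
#'
#' @param path Path to a catalog file; defaults to the bundled GRAS catalog.
#' @return A tibble with columns `name`, `region`, `pattern`.
#' @export
read_motif_catalog <- function(path = grasfam_example("gras_motif_catalog.tsv")) {
  cat <- readr::read_tsv(path, comment = "#", col_types = "ccc", progress = FALSE)
  names(cat) <- c("name", "region", "pattern")
  if (any(!nzchar(cat$pattern))) abort("motif catalog contains an empty pattern")
  cat
}

core_motif_order <- c("LHRI", "VHIID", "LHRII", "PFYRE", "SAW")

# Compile a pattern string to a list of per-position residue sets
# (NULL = wildcard).
compile_pattern <- function(pattern) {
  out <- list()
  chars <- strsplit(pattern, "")[[1L]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- i + which(chars[(i + 1L):length(chars)] == "]")[1L]
      if (is.na(close)) abort(paste0("unclosed [ in pattern ", pattern))
      set <- chars[(i + 1L):(close - 1L)]
      if (length(set) == 0L) abort(paste0("empty alternative set in pattern ", pattern))
      out <- c(out, list(set))
      i <- close + 1L
    } else if (ch %in% c("X", "+")) {
      out <- c(out, list(NULL))
      i <- i + 1L
    } else {
      out <- c(out, list(ch))
      i <- i + 1L
    }
  }
  out
}

#' Scan a protein for a motif pattern
#'
#' Slides the pattern along the sequence; a window's match score is the
#' fraction of non-wildcard pattern positions whose residue matches. All
#' windows scoring at least `min_score` are collected and made
#' non-overlapping greedily, best score first (ties to the leftmost window).
#' A pattern longer than the sequence yields an empty result, not an error.
#'
#' @param protein A sequence string or single-row [protein_records] tibble.
#' @param pattern A pattern string (see [motif_patterns]).
#' @param min_score Minimum match score (default 0.7).
#' @param motif_name Name recorded in the output.
#' @return A tibble of hits: `id`, `motif`, `start`, `end`, `match_score`
#'   (1-based inclusive residue coordinates).
#' @export
#' @examples
#' scan_motif("MKRDELLAALGYKV", "DELLA")
scan_motif <- function(protein, pattern, min_score = 0.7, motif_name = pattern) {
  id <- "protein"
  if (is.data.frame(protein)) { id <- protein$id[1L]; protein <- protein$sequence[1L] }
  if (!nzchar(protein)) abort("cannot scan an empty sequence")
  comp <- compile_pattern(pattern)
  m <- length(comp)
  n <- nchar(protein)
  empty <- tibble::tibble(id = character(), motif = character(),
                          start = integer(), end = integer(),
                          match_score = numeric())
  if (m > n) return(empty)
  chars <- strsplit(protein, "")[[1L]]
  fixed <- which(!vapply(comp, is.null, logical(1)))
  n_windows <- n - m + 1L
  if (length(fixed) == 0L) {
    scores <- rep(1, n_windows)
  } else {
    scores <- rep(0, n_windows)
    for (k in fixed) {
      ok <- chars[k:(k + n_windows - 1L)] %in% comp[[k]]
      scores <- scores + ok
    }
    scores <- scores / length(fixed)
  }
  cand <- which(scores >= min_score)
  if (length(cand) == 0L) return(empty)
  cand <- cand[order(-scores[cand], cand)]
  taken <- logical(n)
  hits <- list()
  for (s in cand) {
    span <- s:(s + m - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      hits <- c(hits, list(tibble::tibble(id = id, motif = motif_name,
                                          start = s, end = s + m - 1L,
                                          match_score = scores[s])))
    }
  }
  dplyr::bind_rows(hits) |> dplyr::arrange(.data$start)
}

#' De-novo conserved windows in a subfamily alignment
#'
#' Finds the maximal runs of at least `min_length` consecutive alignment
#' columns whose per-column identity (fraction of rows carrying the modal
#' residue, with gaps counting against) is at least `min_identity`. Both
#' bounds are inclusive, so a 10-column run at exactly 50% column identity is
#' reported at the defaults. Output is invariant to row order and windows
#' are maximal: none can be extended by one column and still qualify.
#'
#' @param msa An [msa] tibble with at least 2 rows.
#' @param min_identity Minimum per-column modal-residue fraction
#'   (default 0.50).
#' @param min_length Minimum run length in columns (default 10).
#' @return A tibble of windows: `start`, `end` (column indices), `length`,
#'   `mean_identity`, and `identities` (list column of per-column identity).
#' @export
discover_conserved_windows <- function(msa, min_identity = 0.50, min_length = 10L) {
  stopifnot(min_identity > 0, min_identity <= 1, min_length >= 1)
  if (nrow(msa) < 2L) abort("conserved-window discovery needs at least 2 rows")
  mat <- msa_matrix(msa)
  identity <- apply(mat, 2L, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0L) return(0)
    max(table(res)) / length(col)
  })
  ok <- identity >= min_identity
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  tibble::tibble(
    start = starts[keep], end = ends[keep],
    length = r$lengths[keep],
    mean_identity = purrr::map2_dbl(starts[keep], ends[keep],
                                    ~ mean(identity[.x:.y])),
    identities = purrr::map2(starts[keep], ends[keep], ~ identity[.x:.y])
  )
}

#' Annotate a protein against a motif catalog
#'
#' Locates every catalog motif, keeps the hits of the five core GRAS-domain
#' motifs mutually non-overlapping (greedy, best score first), flags catalog
#' motifs with no hit as missing (truncation indicators, e.g. PFYRE and SAW
#' absent from a protein truncated inside the GRAS domain), and warns when
#' the core motifs that are present occur out of their canonical
#' LHRI-VHIID-LHRII-PFYRE-SAW order.
#'
#' @param protein A sequence string or single-row [protein_records] tibble.
#' @param catalog A catalog tibble from [read_motif_catalog()].
#' @param min_score Minimum match score (default 0.7).
#' @return An object of class `motif_annotation`: a list with `id`, `hits`
#'   (tibble ordered along the sequence), `missing_expected` and
#'   `out_of_order` character vectors. See [tidy.motif_annotation()].
#' @export
annotate_motifs <- function(protein, catalog = read_motif_catalog(),
                            min_score = 0.7) {
  id <- "protein"
  if (is.data.frame(protein)) { id <- protein$id[1L]; protein <- protein$sequence[1L] }
  if (!nzchar(protein)) abort("cannot annotate an empty sequence")
  all_hits <- purrr::pmap_dfr(catalog, function(name, region, pattern) {
    scan_motif(protein, pattern, min_score = min_score, motif_name = name)
  })
  if (nrow(all_hits) > 0L) all_hits$id <- id
  # one best hit per motif; core motifs additionally kept non-overlapping
  best <- all_hits |>
    dplyr::group_by(.data$motif) |>
    dplyr::arrange(dplyr::desc(.data$match_score), .data$start, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  core <- best |>
    dplyr::filter(.data$motif %in% core_motif_order) |>
    dplyr::arrange(dplyr::desc(.data$match_score), .data$start)
  taken <- logical(nchar(protein))
  keep_core <- logical(nrow(core))
  for (i in seq_len(nrow(core))) {
    span <- core$start[i]:core$end[i]
    if (!any(taken[span])) { taken[span] <- TRUE; keep_core[i] <- TRUE }
  }
  hits <- dplyr::bind_rows(core[keep_core, ],
                           dplyr::filter(best, !.data$motif %in% core_motif_order)) |>
    dplyr::arrange(.data$start)
  missing <- setdiff(catalog$name, hits$motif)
  core_present <- hits |>
    dplyr::filter(.data$motif %in% core_motif_order) |>
    dplyr::arrange(.data$start)
  canonical <- core_motif_order[core_motif_order %in% core_present$motif]
  out_of_order <- if (!identical(core_present$motif, canonical)) {
    warn(paste0("core GRAS motifs out of canonical order in ", id, ": ",
                paste(core_present$motif, collapse = " > ")))
    core_present$motif
  } else character(0)
  structure(list(id = id, hits = hits, missing_expected = missing,
                 out_of_order = out_of_order),
            class = "motif_annotation")
}

#' @export
print.motif_annotation <- function(x, ...) {
  cat(sprintf("Motif annotation for %s: %d hit(s), %d catalog motif(s) missing\n",
              x$id, nrow(x$hits), length(x$missing_expected)))
  if (length(x$missing_expected) > 0L) {
    cat("  missing:", paste(x$missing_expected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a motif annotation
#'
#' @param x A `motif_annotation`.
#' @param ... Unused.
#' @return The hit tibble, ordered along the sequence.
#' @export
tidy.motif_annotation <- function(x, ...) x$hits

#' Write motif annotations as GFF3 on protein coordinates
#'
#' @param annotations A list of `motif_annotation` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_gff3 <- function(annotations, path) {
  if (inherits(annotations, "motif_annotation")) annotations <- list(annotations)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  for (ann in annotations) {
    h <- ann$hits
    if (nrow(h) == 0L) next
    writeLines(paste(h$id, "grasfam", "protein_motif", h$start, h$end,
                     sprintf("%.3f", h$match_score), ".", ".",
                     paste0("Name=", h$motif), sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}
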