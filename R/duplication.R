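#' Tandem-array detection
#'
#' Finds maximal chains of same-subfamily loci on one chromosome in which
#' consecutive members (ordered by start) are at most `max_gap_bp` apart,
#' measured from the end of one genomic span to the start of the next. The
#' 250 kb default separates genuinely arrayed near-identical copies from
#' same-chromosome subfamily members megabases away. Arrays are maximal and
#' disjoint, each reported array has at least two members, and the calls are
#' invariant to input row order.
#'
#' @param loci A [locus_table] tibble.
#' @param subfamilies A tibble with columns `locus_id` and `subfamily` (or
#'   `id` and `subfamily`). Loci without a label are an error.
#' @param max_gap_bp Maximum gap between consecutive members (default 250000).
#' @return A tibble with one row per array member: `array`, `kind`,
#'   `chromosome`, `subfamily`, `locus_id`, `start`, `end`.
#' @export
tandem_arrays <- function(loci, subfamilies, max_gap_bp = 250000) {
  spans <- locus_lengths(loci) |>
    dplyr::left_join(
      loci |> dplyr::group_by(.data$locus_id) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end)),
      by = "locus_id"
    )
  spans <- join_subfamilies(spans, subfamilies)
  spans <- spans |>
    dplyr::arrange(.data$chromosome, .data$start, .data$locus_id) |>
    dplyr::group_by(.data$chromosome, .data$subfamily) |>
    dplyr::mutate(
      gap = .data$start - dplyr::lag(.data$end),
      chain = cumsum(dplyr::coalesce(.data$gap > max_gap_bp, TRUE))
    ) |>
    dplyr::group_by(.data$chromosome, .data$subfamily, .data$chain) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::ungroup()
  if (nrow(spans) == 0L) {
    return(tibble::tibble(array = integer(), kind = character(),
                          chromosome = integer(), subfamily = character(),
                          locus_id = character(), start = numeric(),
                          end = numeric()))
  }
  spans |>
    dplyr::mutate(array = dplyr::dense_rank(
      paste(.data$chromosome, .data$subfamily, .data$chain, sep = "/"))) |>
    dplyr::transmute(.data$array, kind = "tandem", .data$chromosome,
                     .data$subfamily, .data$locus_id, .data$start, .data$end) |>
    dplyr::arrange(.data$array, .data$start)
}

join_subfamilies <- function(spans, subfamilies) {
  if ("id" %in% names(subfamilies) && !"locus_id" %in% names(subfamilies)) {
    subfamilies <- dplyr::rename(subfamilies, locus_id = "id")
  }
  out <- dplyr::left_join(spans,
                          dplyr::select(subfamilies, "locus_id", "subfamily"),
                          by = "locus_id")
  if (anyNA(out$subfamily)) {
    abort(paste0("no subfamily label for locus ",
                 out$locus_id[is.na(out$subfamily)][1L]))
  }
  out
}

#' Segmental-duplication calls against a paralogous-segment map
#'
#' Two same-subfamily loci are called a segmental pair when one falls inside
#' interval A and the other inside interval B of a map pair (in either
#' orientation; the map is symmetric). A locus falls inside an interval when
#' its genomic span is fully contained, optionally relaxed by
#' `tolerance_bp` on both interval ends for loci sitting just beside a
#' presumed paralogous segment (default 0: strict containment).
#'
#' @param loci A [locus_table] tibble.
#' @param subfamilies Subfamily labels as in [tandem_arrays()].
#' @param map A segment-map tibble from [read_segment_map()].
#' @param tolerance_bp Interval slack in bp (default 0).
#' @return A tibble with one row per called pair: `pair`, `kind`,
#'   `subfamily`, `locus_a`, `chrom_a`, `locus_b`, `chrom_b`, `map_row`.
#' @export
segmental_pairs <- function(loci, subfamilies, map, tolerance_bp = 0) {
  validate_segment_map(map)
  spans <- locus_lengths(loci) |>
    dplyr::left_join(
      loci |> dplyr::group_by(.data$locus_id) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end)),
      by = "locus_id"
    )
  spans <- join_subfamilies(spans, subfamilies)
  inside <- function(chrom, istart, iend) {
    spans$chromosome == chrom &
      spans$start >= istart - tolerance_bp &
      spans$end <= iend + tolerance_bp
  }
  calls <- list()
  for (k in seq_len(nrow(map))) {
    in_a <- which(inside(map$chrom_a[k], map$start_a[k], map$end_a[k]))
    in_b <- which(inside(map$chrom_b[k], map$start_b[k], map$end_b[k]))
    for (i in in_a) {
      for (j in in_b) {
        if (spans$locus_id[i] == spans$locus_id[j]) next
        if (spans$subfamily[i] != spans$subfamily[j]) next
        pair <- sort(c(spans$locus_id[i], spans$locus_id[j]))
        calls <- c(calls, list(tibble::tibble(
          subfamily = spans$subfamily[i],
          locus_a = pair[1L],
          chrom_a = spans$chromosome[match(pair[1L], spans$locus_id)],
          locus_b = pair[2L],
          chrom_b = spans$chromosome[match(pair[2L], spans$locus_id)],
          map_row = k
        )))
      }
    }
  }
  out <- dplyr::bind_rows(calls)
  if (nrow(out) == 0L) {
    return(tibble::tibble(pair = integer(), kind = character(),
                          subfamily = character(), locus_a = character(),
                          chrom_a = integer(), locus_b = character(),
                          chrom_b = integer(), map_row = integer()))
  }
  out |>
    dplyr::distinct(.data$subfamily, .data$locus_a, .data$locus_b,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$locus_a, .data$locus_b) |>
    dplyr::mutate(pair = dplyr::row_number(), kind = "segmental") |>
    dplyr::select("pair", "kind", "subfamily", "locus_a", "chrom_a",
                  "locus_b", "chrom_b", "map_row")
}
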