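#' Per-locus structure measures
#'
#' For each locus: the exon count, the spliced length (sum of segment
#' lengths, in bp) and the genomic span (`max(end) - min(start) + 1`). The
#' span always contains the spliced length; the two coincide exactly for
#' intronless (single-exon) genes.
#'
#' @param loci A [locus_table] tibble.
#' @return A tibble with one row per locus: `locus_id`, `short_name`,
#'   `chromosome`, `strand`, `exons`, `spliced_length`, `genomic_span`.
#' @export
#' @examples
#' read_locus_table(grasfam_example("gras_table1.tsv")) |> locus_lengths()
locus_lengths <- function(loci) {
  validate_locus_table(loci)
  loci |>
    dplyr::group_by(.data$locus_id, .data$short_name, .data$chromosome, .data$strand) |>
    dplyr::summarise(
      exons = dplyr::n(),
      spliced_length = sum(.data$end - .data$start + 1),
      genomic_span = max(.data$end) - min(.data$start) + 1,
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$locus_id, unique(loci$locus_id)))
}

#' Exon count of one locus
#'
#' @param loci A [locus_table] tibble.
#' @param locus_id Locus accession.
#' @return Integer number of exon segments.
#' @export
exon_count <- function(loci, locus_id) {
  sum(loci$locus_id == locus_id)
}

#' Spliced length of one locus (bp)
#'
#' @inheritParams exon_count
#' @export
spliced_length <- function(loci, locus_id) {
  lt <- loci[loci$locus_id == locus_id, ]
  if (nrow(lt) == 0L) abort(paste0("unknown locus ", locus_id))
  sum(lt$end - lt$start + 1)
}

#' Genomic span of one locus (bp)
#'
#' @inheritParams exon_count
#' @export
genomic_span <- function(loci, locus_id) {
  lt <- loci[loci$locus_id == locus_id, ]
  if (nrow(lt) == 0L) abort(paste0("unknown locus ", locus_id))
  max(lt$end) - min(lt$start) + 1
}

#' Gene-structure summary of a family
#'
#' Reproduces the family-level structure statistics: locus count, intronless
#' count and percentage (rounded half-even to 2 decimals), the exon-count
#' histogram, per-chromosome counts, the chromosomes bearing exactly one
#' locus, and the per-locus length table. An empty table yields an all-zero
#' summary rather than an error.
#'
#' @param loci A [locus_table] tibble.
#' @return An object of class `structure_summary`; see [tidy.structure_summary()]
#'   and [glance.structure_summary()].
#' @export
#' @examples
#' read_locus_table(grasfam_example("gras_table1.tsv")) |>
#'   summarize_structure() |>
#'   glance()
summarize_structure <- function(loci) {
  lengths <- if (nrow(loci) == 0L) {
    tibble::tibble(locus_id = character(), short_name = character(),
                   chromosome = integer(), strand = character(),
                   exons = integer(), spliced_length = numeric(),
                   genomic_span = numeric())
  } else {
    locus_lengths(loci)
  }
  n_loci <- nrow(lengths)
  n_intronless <- sum(lengths$exons == 1L)
  per_chrom <- lengths |> dplyr::count(.data$chromosome, name = "n_loci")
  out <- list(
    n_loci = n_loci,
    n_intronless = n_intronless,
    pct_intronless = if (n_loci > 0L) round(100 * n_intronless / n_loci, 2) else NA_real_,
    exon_count_histogram = lengths |> dplyr::count(.data$exons, name = "n_loci"),
    per_chromosome_counts = per_chrom,
    singleton_chromosomes = sort(per_chrom$chromosome[per_chrom$n_loci == 1L]),
    length_table = lengths
  )
  structure(out, class = "structure_summary")
}

#' @export
print.structure_summary <- function(x, ...) {
  cat("Gene-family structure summary\n")
  cat(sprintf("  loci: %d  intronless: %d (%.2f%%)\n",
              x$n_loci, x$n_intronless, x$pct_intronless))
  cat(sprintf("  chromosomes: %d  single-locus chromosomes: %s\n",
              nrow(x$per_chromosome_counts),
              paste(x$singleton_chromosomes, collapse = ", ")))
  invisible(x)
}

#' Tidy a structure summary
#'
#' @param x A `structure_summary`.
#' @param ... Unused.
#' @return The per-locus length table as a tibble.
#' @export
tidy.structure_summary <- function(x, ...) {
  x$length_table
}

#' One-row glance at a structure summary
#'
#' @inheritParams tidy.structure_summary
#' @return A one-row tibble of family-level counts.
#' @export
glance.structure_summary <- function(x, ...) {
  tibble::tibble(
    n_loci = x$n_loci,
    n_intronless = x$n_intronless,
    n_intron_containing = x$n_loci - x$n_intronless,
    pct_intronless = x$pct_intronless,
    n_chromosomes = nrow(x$per_chromosome_counts),
    n_singleton_chromosomes = length(x$singleton_chromosomes)
  )
}

#' Subfamily label from a gene symbol
#'
#' Derives the subfamily from a member symbol by stripping the member suffix:
#' a single trailing lowercase letter when present (`SCL3a` -> `SCL3`,
#' `GRASV1b` -> `GRASV1`), otherwise trailing digits (`PAT1` -> `PAT`,
#' `LISCL12` -> `LISCL`). `RGA` symbols map to the DELLA subfamily, the
#' gibberellin-signaling repressors they belong to.
#'
#' @param short_name Character vector of gene symbols.
#' @return Character vector of subfamily labels.
#' @export
#' @examples
#' subfamily_from_symbol(c("PAT1", "RGA5", "GRASV1b", "SCL26a", "HAM2"))
subfamily_from_symbol <- function(short_name) {
  base <- ifelse(grepl("[a-z]$", short_name),
                 sub("[a-z]$", "", short_name),
                 sub("[0-9]+$", "", short_name))
  ifelse(grepl("^RGA", base), "DELLA", base)
}
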