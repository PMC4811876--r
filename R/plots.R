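#' Plot family structure statistics
#'
#' Exon-count histogram and per-chromosome locus counts for a structure
#' summary.
#'
#' @param object A `structure_summary` from [summarize_structure()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_summary <- function(object, ...) {
  counts <- dplyr::bind_rows(
    object$exon_count_histogram |>
      dplyr::transmute(panel = "exons per locus", x = as.character(.data$exons),
                       n = .data$n_loci),
    object$per_chromosome_counts |>
      dplyr::transmute(panel = "loci per chromosome",
                       x = sprintf("%02d", .data$chromosome), n = .data$n_loci)
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$x, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "loci") +
    ggplot2::theme_minimal()
}

#' Orthology matrix in the three-category scheme
#'
#' Genes by genomes, colored like cross-genome family comparisons: green for
#' a one-to-one ortholog, grey for homology without a one-to-one partner,
#' white for no retained match.
#'
#' @param calls A tibble of [classify_orthologs()] /
#'   [orthology_matrix()] rows.
#' @return A ggplot object.
#' @export
plot_orthology_matrix <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$target_genome, y = .data$query_id,
                                      fill = .data$category)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_manual(values = c(one_to_one = "#2e7d32",
                                          homolog_no_ortholog = "grey60",
                                          absent = "white"),
                               drop = FALSE) +
    ggplot2::labs(x = "genome", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Expression heatmap matrix
#'
#' Condition-averaged log2 intensities as a tile heatmap, mirroring the data
#' layout of tissue-atlas expression figures.
#'
#' @param avg A condition-averaged tibble from [average_replicates()].
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(avg) {
  long <- tidyr::pivot_longer(avg, -"gene", names_to = "condition",
                              values_to = "log2_intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$gene,
                                     fill = .data$log2_intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#fff7ec", high = "#7f0000") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
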