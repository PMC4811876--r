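#' Expression matrices and replicate designs
#'
#' Expression values are RMA-normalized log2 intensities in a tibble whose
#' first column is `gene` and whose remaining columns are samples. The
#' replicate design maps each sample to a condition and carries the
#' condition metadata: `sample`, `condition`, `tissue`, `po_id` (Plant
#' Ontology term, optional), `platform`.
#'
#' @name expression_data
NULL

#' @rdname expression_data
#' @param path Path to a tab-separated genes x samples matrix (header row,
#'   first column gene IDs).
#' @return `read_expression_matrix()`: a tibble with column `gene` and one
#'   numeric column per sample.
#' @export
read_expression_matrix <- function(path) {
  mat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(mat)[1L] <- "gene"
  mat$gene <- as.character(mat$gene)
  mat[-1L] <- lapply(mat[-1L], as.numeric)
  if (anyDuplicated(mat$gene)) abort("duplicate gene IDs in expression matrix")
  if (any(!is.finite(as.matrix(mat[, -1L])))) {
    abort("expression matrix contains non-finite values")
  }
  mat
}

#' @rdname expression_data
#' @export
read_expression_design <- function(path) {
  design <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  required <- c("sample", "condition", "tissue")
  missing <- setdiff(required, names(design))
  if (length(missing) > 0L) {
    abort(paste0("design is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"po_id" %in% names(design)) design$po_id <- NA_character_
  if (!"platform" %in% names(design)) design$platform <- NA_character_
  design
}

#' Average replicates into condition profiles
#'
#' Arithmetic mean in log2 space of the replicates of each condition
#' (typically 3 or 4 per condition). Every sample column must be assigned a
#' condition by the design; condition metadata (tissue, PO term, platform)
#' is propagated as the `conditions` attribute of the result.
#'
#' @param expr An expression tibble (see [expression_data]).
#' @param design A replicate-design tibble.
#' @return A tibble `gene` x condition with attribute `conditions` (a tibble
#'   `condition`, `tissue`, `po_id`, `platform`).
#' @export
average_replicates <- function(expr, design) {
  samples <- setdiff(names(expr), "gene")
  unassigned <- setdiff(samples, design$sample)
  if (length(unassigned) > 0L) {
    abort(paste0("sample(s) without a condition in the design: ",
                 paste(unassigned, collapse = ", ")))
  }
  design <- design[design$sample %in% samples, ]
  if (nrow(design) == 0L) abort("no design rows match the matrix samples")
  long <- expr |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value") |>
    dplyr::inner_join(design, by = "sample")
  avg <- long |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  avg <- avg[match(expr$gene, avg$gene), ]
  cond_meta <- design |>
    dplyr::distinct(.data$condition, .data$tissue, .data$po_id, .data$platform)
  if (anyDuplicated(cond_meta$condition)) {
    warn("condition with inconsistent metadata across replicates; keeping the first")
    cond_meta <- cond_meta[!duplicated(cond_meta$condition), ]
  }
  attr(avg, "conditions") <- cond_meta
  avg
}

#' Plant Ontology attribution by intensity threshold
#'
#' A gene is attributed the PO term of a tissue when its condition-averaged
#' intensity in any condition of that tissue reaches the threshold. The
#' default threshold of log2 = 8 corresponds to a raw intensity of 256
#' exactly, so the comparison is inclusive (`>=`) by default: a gene at
#' exactly 8.0 is attributed. Set `inclusive = FALSE` for a strict gate.
#'
#' @param avg A condition-averaged tibble from [average_replicates()].
#' @param conditions Condition metadata; defaults to the `conditions`
#'   attribute of `avg`.
#' @param threshold Log2 intensity threshold (default 8).
#' @param inclusive Attribute at exactly the threshold (default TRUE).
#' @return A tibble `gene`, `po_id`, `tissue` (one row per attribution).
#' @export
po_attribution <- function(avg, conditions = attr(avg, "conditions"),
                           threshold = 8, inclusive = TRUE) {
  if (is.null(conditions)) abort("condition metadata required for PO attribution")
  long <- avg |>
    tidyr::pivot_longer(-"gene", names_to = "condition", values_to = "value") |>
    dplyr::inner_join(conditions, by = "condition") |>
    dplyr::filter(!is.na(.data$po_id))
  hit <- if (inclusive) long$value >= threshold else long$value > threshold
  long[hit, ] |>
    dplyr::distinct(.data$gene, .data$po_id, .data$tissue)
}

#' Strict-threshold co-expression clustering
#'
#' Hierarchical clustering of condition-averaged profiles with Pearson
#' correlation distance (`1 - PCC`) and average linkage. Genes share a
#' cluster only when every pair within it is closer than `cutoff`
#' (a complete-pair reading of "distance lower than 0.2 between each
#' other"): the average-linkage tree is cut strictly below the cutoff and
#' clusters violating the pairwise bound are re-split by a complete-linkage
#' cut, whose merge heights are exactly the maximal pairwise distances.
#' Constant-profile genes have no defined correlation and are excluded with
#' a warning. Fewer than two conditions is an error.
#'
#' @param avg A condition-averaged tibble from [average_replicates()] (or
#'   any `gene` x condition tibble).
#' @param cutoff Strict pairwise distance bound (default 0.2).
#' @return A tibble `gene`, `cluster` (NA for unclustered genes); singleton
#'   clusters are reported as unclustered. The pairwise distance matrix of
#'   the clustered-eligible genes is attached as attribute `distances`.
#' @export
coexpression_clusters <- function(avg, cutoff = 0.2) {
  stopifnot(cutoff >= 0, cutoff <= 2)
  mat <- as.matrix(avg[, setdiff(names(avg), "gene"), drop = FALSE])
  rownames(mat) <- avg$gene
  if (ncol(mat) < 2L) abort("co-expression clustering needs at least 2 conditions")
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("constant expression profile(s) excluded (undefined correlation): ",
                paste(rownames(mat)[sds == 0], collapse = ", ")))
  }
  keep <- sds > 0
  out <- tibble::tibble(gene = avg$gene, cluster = NA_integer_)
  if (sum(keep) >= 2L) {
    D <- 1 - cor(t(mat[keep, , drop = FALSE]))
    # strict bound: distances within 1e-9 of the cutoff count as at the
    # cutoff and are excluded, so a pair at exactly the cutoff never
    # co-clusters regardless of floating-point rounding in the correlation
    eps_cut <- cutoff - 1e-9
    grp <- cutree(hclust(as.dist(D), method = "average"), h = eps_cut)
    # enforce the strict complete-pair bound within every reported cluster
    next_id <- 0L
    final <- rep(NA_integer_, length(grp))
    for (g in unique(grp)) {
      members <- which(grp == g)
      if (length(members) < 2L) next
      sub <- D[members, members, drop = FALSE]
      if (max(sub) < eps_cut) {
        next_id <- next_id + 1L
        final[members] <- next_id
      } else {
        regrp <- cutree(hclust(as.dist(sub), method = "complete"), h = eps_cut)
        for (g2 in unique(regrp)) {
          m2 <- members[regrp == g2]
          if (length(m2) >= 2L) {
            next_id <- next_id + 1L
            final[m2] <- next_id
          }
        }
      }
    }
    out$cluster[match(rownames(mat)[keep], out$gene)] <- final
    attr(out, "distances") <- D
  }
  out
}

#' Co-expression partners of one gene
#'
#' @param clusters A tibble from [coexpression_clusters()].
#' @param gene A gene ID present in `clusters`.
#' @return Character vector of the other members of the gene's cluster
#'   (empty when the gene is unclustered). Partnership is symmetric.
#' @export
coexpression_partners <- function(clusters, gene) {
  if (!gene %in% clusters$gene) abort(paste0("unknown gene ", gene))
  cl <- clusters$cluster[clusters$gene == gene]
  if (is.na(cl)) return(character(0))
  setdiff(clusters$gene[!is.na(clusters$cluster) & clusters$cluster == cl], gene)
}
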