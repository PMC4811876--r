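#' Multiple alignments
#'
#' A multiple alignment is a tibble with columns `id` and `aligned` (gapped
#' sequences of equal length, `-` for gaps). Removing the gaps of row *i*
#' always reproduces input sequence *i*.
#'
#' @name msa
NULL

msa_matrix <- function(msa) {
  widths <- nchar(msa$aligned)
  if (length(unique(widths)) > 1L) abort("alignment rows have unequal lengths")
  mat <- do.call(rbind, strsplit(msa$aligned, ""))
  rownames(mat) <- msa$id
  mat
}

msa_from_matrix <- function(mat) {
  tibble::tibble(id = rownames(mat),
                 aligned = unname(apply(mat, 1L, paste, collapse = "")))
}

encode_msa <- function(msa, alphabet) {
  mat <- msa_matrix(msa)
  out <- matrix(match(mat, alphabet), nrow = nrow(mat))
  out[mat == "-"] <- 0L
  if (anyNA(out)) {
    x <- match("X", alphabet)
    out[is.na(out)] <- x
  }
  rownames(out) <- rownames(mat)
  out
}

profile_freqs <- function(aln, n_letters) {
  # residue frequencies per column; gap mass is dropped (scores against a
  # gap-heavy column are correspondingly down-weighted)
  L <- ncol(aln)
  F <- matrix(0, nrow = n_letters, ncol = L)
  for (i in seq_len(nrow(aln))) {
    row <- aln[i, ]
    nz <- row > 0L
    F[cbind(row[nz], which(nz))] <- F[cbind(row[nz], which(nz))] + 1
  }
  F / nrow(aln)
}

#' Progressive multiple sequence alignment
#'
#' A plain guide-tree progressive aligner: pairwise local-alignment
#' identities give a distance matrix, UPGMA (average linkage) gives the merge
#' order, and profiles are merged by affine-gap dynamic programming over
#' column-vs-column substitution scores with free end gaps. There is no
#' iterative refinement; within low-divergence subfamilies (where motif
#' discovery operates) this is adequate. For exactly two ungapped sequences
#' the result is the optimal global alignment with free end gaps.
#'
#' @param records A [protein_records] tibble with at least two rows.
#' @param params An [alignment_params()] object.
#' @return An [msa] tibble in input row order.
#' @export
progressive_msa <- function(records, params = alignment_params()) {
  n <- nrow(records)
  if (n < 2L) abort("progressive_msa needs at least 2 records")
  S <- params$substitution_matrix
  alphabet <- rownames(S)
  enc <- lapply(records$sequence, encode_sequence, alphabet = alphabet)

  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      hit <- cpp_align_local(enc[[i]], enc[[j]], S, params$gap_open, params$gap_extend)
      idn <- if (length(hit$a_idx) > 0L) {
        both <- hit$a_idx > 0L & hit$b_idx > 0L
        sum(enc[[i]][hit$a_idx[both]] == enc[[j]][hit$b_idx[both]]) / length(hit$a_idx)
      } else 0
      D[i, j] <- D[j, i] <- 1 - idn
    }
  }

  profiles <- lapply(seq_len(n), function(i) {
    list(ids = records$id[i], aln = matrix(enc[[i]], nrow = 1L))
  })
  if (n == 2L) {
    merged <- merge_profiles(profiles[[1L]], profiles[[2L]], S, params)
  } else {
    tree <- hclust(as.dist(D), method = "average")
    merged_list <- vector("list", n - 1L)
    get_cluster <- function(k) if (k < 0L) profiles[[-k]] else merged_list[[k]]
    for (step in seq_len(n - 1L)) {
      merged_list[[step]] <- merge_profiles(get_cluster(tree$merge[step, 1L]),
                                            get_cluster(tree$merge[step, 2L]),
                                            S, params)
    }
    merged <- merged_list[[n - 1L]]
  }
  aln <- merged$aln[match(records$id, merged$ids), , drop = FALSE]
  chars <- matrix("-", nrow = nrow(aln), ncol = ncol(aln))
  chars[aln > 0L] <- alphabet[aln[aln > 0L]]
  rownames(chars) <- records$id
  msa_from_matrix(chars)
}

merge_profiles <- function(p1, p2, S, params) {
  nl <- nrow(S)
  F1 <- profile_freqs(p1$aln, nl)
  F2 <- profile_freqs(p2$aln, nl)
  SM <- crossprod(F1, S %*% F2)
  path <- cpp_profile_align(SM, params$gap_open, params$gap_extend, TRUE)
  L <- length(path$a_idx)
  out <- matrix(0L, nrow = nrow(p1$aln) + nrow(p2$aln), ncol = L)
  a_cols <- path$a_idx
  b_cols <- path$b_idx
  out[seq_len(nrow(p1$aln)), a_cols > 0L] <- p1$aln[, a_cols[a_cols > 0L], drop = FALSE]
  out[nrow(p1$aln) + seq_len(nrow(p2$aln)), b_cols > 0L] <-
    p2$aln[, b_cols[b_cols > 0L], drop = FALSE]
  list(ids = c(p1$ids, p2$ids), aln = out)
}

#' Remove low-coverage alignment columns
#'
#' Columns whose non-gap fraction is below `min_site_coverage` are
#' eliminated; the comparison is strict, so at the default 0.95 a column with
#' exactly 95% site coverage is kept. Removing every column signals an
#' unusable alignment and is an error.
#'
#' @param msa An [msa] tibble.
#' @param min_site_coverage Minimum non-gap fraction a column must reach to
#'   be kept (default 0.95).
#' @return The masked [msa] tibble (row order preserved).
#' @export
mask_columns <- function(msa, min_site_coverage = 0.95) {
  stopifnot(min_site_coverage > 0, min_site_coverage <= 1)
  mat <- msa_matrix(msa)
  coverage <- colMeans(mat != "-")
  keep <- coverage >= min_site_coverage
  if (!any(keep)) abort("column masking removed every alignment column")
  msa_from_matrix(mat[, keep, drop = FALSE])
}
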