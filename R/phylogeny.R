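#' Phylogeny parameters
#'
#' @param min_site_coverage Fraction of non-gap sites a column needs to
#'   survive masking (default 0.95; strict "less than" removal).
#' @param bootstrap_replicates Number of column-resampling replicates
#'   (default 100).
#' @param collapse_below Support fraction below which consensus partitions
#'   are collapsed to polytomies (default 0.30; a partition at exactly 30%
#'   support is retained).
#' @param distance_model `"p_distance"` or `"jtt_corrected"`.
#' @param seed Integer seed for the column resampling.
#' @return A list of class `phylo_params`.
#' @export
phylo_params <- function(min_site_coverage = 0.95, bootstrap_replicates = 100,
                         collapse_below = 0.30,
                         distance_model = c("jtt_corrected", "p_distance"),
                         seed = 1L) {
  stopifnot(min_site_coverage > 0, min_site_coverage <= 1,
            collapse_below >= 0, collapse_below <= 1,
            bootstrap_replicates >= 1)
  structure(list(min_site_coverage = min_site_coverage,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 collapse_below = collapse_below,
                 distance_model = match.arg(distance_model),
                 seed = as.integer(seed)),
            class = "phylo_params")
}

#' Pairwise distances from a masked alignment
#'
#' `p_distance` is the mismatch fraction over mutually ungapped columns.
#' `jtt_corrected` applies the standard protein distance correction
#' `d = -ln(1 - p - 0.2 p^2)`, whose expansion is calibrated to the expected
#' substitution curve of empirical amino-acid models; it is convex, so the
#' corrected distance is never below p. Near the saturation point
#' (p above roughly 0.85) the argument of the logarithm is floored at 1e-4,
#' capping the distance at about 9.2 substitutions/site. A pair with zero
#' mutually ungapped columns is an error naming the pair.
#'
#' @param msa An [msa] tibble (typically after [mask_columns()]).
#' @param model `"p_distance"` or `"jtt_corrected"`.
#' @return A symmetric distance matrix with zero diagonal, labeled by
#'   sequence ID.
#' @export
msa_distances <- function(msa, model = c("p_distance", "jtt_corrected")) {
  model <- match.arg(model)
  if (nrow(msa) < 2L) abort("distance computation needs at least 2 sequences")
  enc <- encode_msa(msa, aa_letters_x())
  res <- cpp_pdist(enc)
  p <- res$p
  if (anyNA(p)) {
    bad <- which(is.na(p), arr.ind = TRUE)[1L, ]
    abort(paste0("no mutually ungapped columns between ", msa$id[bad[1L]],
                 " and ", msa$id[bad[2L]]))
  }
  d <- if (model == "p_distance") p else -log(pmax(1 - p - 0.2 * p^2, 1e-4))
  dimnames(d) <- list(msa$id, msa$id)
  d
}

aa_letters_x <- function() c(aa_letters, "X")

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]). Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with the deficit moved to the sibling edge so that leaf-to-leaf path
#' lengths through the parent are preserved.
#'
#' @param distances Symmetric distance matrix over at least three taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(distances) {
  if (nrow(distances) < 3L) abort("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(distances))
  clamp_negative_edges(tr)
}

clamp_negative_edges <- function(tr) {
  # one pass over the edges that were negative on entry; a sibling pushed
  # negative by the transfer is floored afterwards rather than re-balanced,
  # so the adjustment always terminates
  for (e in which(tr$edge.length < 0)) {
    deficit <- tr$edge.length[e]
    if (deficit >= 0) next
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sibs) > 0L) {
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Canonical split representation: for each internal edge, the tip set on the
# side NOT containing the reference tip (the alphabetically first label), as
# a key string. Invariant to leaf order and to where the tree is rooted.
canonical_splits <- function(tr, labels) {
  n <- length(labels)
  parts <- ape::prop.part(tr)
  plabs <- attr(parts, "labels")
  ref <- sort(labels)[1L]
  keys <- character(0)
  sizes <- integer(0)
  sets <- list()
  for (p in parts) {
    tipset <- match(plabs[p], labels)
    if (match(ref, labels) %in% tipset) tipset <- setdiff(seq_len(n), tipset)
    if (length(tipset) < 2L || length(tipset) > n - 2L) next
    key <- paste(sort(tipset), collapse = ",")
    if (!key %in% keys) {
      keys <- c(keys, key)
      sizes <- c(sizes, length(tipset))
      sets <- c(sets, list(sort(tipset)))
    }
  }
  list(keys = keys, sets = sets)
}

#' Bootstrap consensus tree
#'
#' Columns of the (masked) alignment are resampled with replacement for each
#' replicate, a neighbor-joining tree is built per replicate, and partitions
#' reproduced in at least `collapse_below` of the replicates are assembled
#' greedily (by decreasing support) into an extended majority-style consensus;
#' partitions below the floor are collapsed to polytomies. Support
#' percentages are recorded as internal node labels. Replicates whose
#' resampled alignment leaves some pair with no mutually ungapped column are
#' skipped with a warning and the support denominator adjusted.
#'
#' @param msa An [msa] tibble (mask first with [mask_columns()]).
#' @param params A [phylo_params()] object; `params$seed` makes the
#'   resampling reproducible.
#' @return A `phylo` tree with node labels holding support in \[0, 100\];
#'   attribute `n_replicates_used` records the denominator.
#' @export
bootstrap_consensus <- function(msa, params = phylo_params()) {
  n <- nrow(msa)
  if (n < 3L) abort("bootstrap consensus needs at least 3 sequences")
  # canonical row order: neighbor joining breaks exact distance ties by
  # index, so supports are made invariant to the input leaf order by
  # computing every replicate on the label-sorted alignment
  msa <- msa[order(msa$id), ]
  enc <- encode_msa(msa, aa_letters_x())
  L <- ncol(enc)
  labels <- msa$id
  counts <- new.env(parent = emptyenv())
  sets <- new.env(parent = emptyenv())
  used <- 0L
  set.seed(params$seed)
  for (r in seq_len(params$bootstrap_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- cpp_pdist(enc[, cols, drop = FALSE])
    if (anyNA(res$p)) {
      warn(sprintf("bootstrap replicate %d skipped: degenerate distance matrix", r))
      next
    }
    p <- res$p
    d <- if (params$distance_model == "p_distance") p else
      -log(pmax(1 - p - 0.2 * p^2, 1e-4))
    dimnames(d) <- list(labels, labels)
    tr <- nj_tree(d)
    sp <- canonical_splits(tr, labels)
    for (k in seq_along(sp$keys)) {
      key <- sp$keys[k]
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      if (is.null(sets[[key]])) sets[[key]] <- sp$sets[[k]]
    }
    used <- used + 1L
  }
  if (used == 0L) abort("every bootstrap replicate was degenerate")

  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], integer(1))
  support <- 100 * freq / used
  # inclusive at the floor, robust to rounding in collapse_below * 100
  keep <- support >= params$collapse_below * 100 - 1e-9
  keys <- keys[keep]; support <- support[keep]
  splits <- lapply(keys, function(k) sets[[k]])
  sizes <- vapply(splits, length, integer(1))
  # leaf-order-invariant tie-break: the sorted label string of the split side
  split_key <- vapply(splits, function(s) paste(sort(labels[s]), collapse = "|"),
                      character(1))
  ord <- order(-support, sizes, split_key)
  splits <- splits[ord]; support <- support[ord]

  kept <- list(); kept_support <- numeric(0)
  for (i in seq_along(splits)) {
    s <- splits[[i]]
    compatible <- all(vapply(kept, function(k) {
      ov <- length(intersect(k, s))
      ov == 0L || ov == length(k) || ov == length(s)
    }, logical(1)))
    if (compatible) {
      kept <- c(kept, list(s))
      kept_support <- c(kept_support, support[i])
    }
  }
  tr <- build_tree_from_clades(labels, kept, kept_support)
  attr(tr, "n_replicates_used") <- used
  tr
}

# Assemble a tree from compatible nested clades (tip-index sets), writing the
# support of each clade as its internal node label.
build_tree_from_clades <- function(labels, clades, supports) {
  n <- length(labels)
  m <- length(clades)
  # smallest clade strictly containing clade i (0 = root); strict nesting is
  # well-defined because the kept clades are pairwise compatible and distinct
  parent <- integer(m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j != i && length(clades[[j]]) > length(clades[[i]]) &&
          all(clades[[i]] %in% clades[[j]]) &&
          (parent[i] == 0L ||
           length(clades[[j]]) < length(clades[[parent[i]]]))) {
        parent[i] <- j
      }
    }
  }
  tip_owner <- integer(n) # smallest clade containing each tip (0 = root)
  for (t in seq_len(n)) {
    for (j in seq_len(m)) {
      if (t %in% clades[[j]] && (tip_owner[t] == 0L ||
          length(clades[[j]]) < length(clades[[tip_owner[t]]]))) {
        tip_owner[t] <- j
      }
    }
  }
  emit <- function(node) {
    kids <- which(parent == node)
    if (node != 0L) kids <- setdiff(kids, node)
    parts <- c(
      vapply(kids, function(k) paste0(emit(k), format(round(supports[k], 1))),
             character(1)),
      labels[tip_owner == node]
    )
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(emit(0L), ";"))
}

#' Reference-anchored subfamily assignment
#'
#' Each unlabeled leaf receives the subfamily label of the smallest retained
#' clade (a side of a post-collapse partition) that contains the leaf and at
#' least one anchor, provided the anchors inside that clade carry exactly one
#' label; leaves whose smallest anchored clade mixes labels, and leaves in no
#' anchored clade (for instance on a fully collapsed star tree), stay
#' unassigned. An anchor missing from the tree is an error.
#'
#' @param tree A `phylo` tree (e.g. from [bootstrap_consensus()]).
#' @param anchors Either a tibble with columns `id` and `subfamily`, or a
#'   named character vector `id -> subfamily`.
#' @return A tibble with columns `id`, `subfamily` (NA when unassigned) and
#'   `is_anchor`.
#' @export
assign_subfamilies <- function(tree, anchors) {
  if (is.data.frame(anchors)) {
    anchors <- setNames(anchors$subfamily, anchors$id)
  }
  labels <- tree$tip.label
  missing <- setdiff(names(anchors), labels)
  if (length(missing) > 0L) {
    abort(paste0("anchor(s) missing from tree: ", paste(missing, collapse = ", ")))
  }
  n <- length(labels)
  parts <- ape::prop.part(tree)
  plabs <- attr(parts, "labels")
  sides <- list()
  for (p in parts) {
    tipset <- sort(match(plabs[p], labels))
    if (length(tipset) >= 2L && length(tipset) <= n - 1L && length(tipset) < n) {
      sides <- c(sides, list(tipset))
    }
    comp <- setdiff(seq_len(n), tipset)
    if (length(comp) >= 2L && length(comp) <= n - 1L) {
      sides <- c(sides, list(sort(comp)))
    }
  }
  sides <- unique(sides)
  anchor_idx <- match(names(anchors), labels)
  out <- purrr::map_dfr(seq_len(n), function(i) {
    lab <- labels[i]
    if (lab %in% names(anchors)) {
      return(tibble::tibble(id = lab, subfamily = unname(anchors[lab]),
                            is_anchor = TRUE))
    }
    containing <- Filter(function(s) i %in% s && any(anchor_idx %in% s), sides)
    if (length(containing) == 0L) {
      return(tibble::tibble(id = lab, subfamily = NA_character_, is_anchor = FALSE))
    }
    smallest <- containing[[which.min(vapply(containing, length, integer(1)))]]
    labs_in <- unique(unname(anchors[names(anchors)[anchor_idx %in% smallest]]))
    tibble::tibble(id = lab,
                   subfamily = if (length(labs_in) == 1L) labs_in else NA_character_,
                   is_anchor = FALSE)
  })
  out
}
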