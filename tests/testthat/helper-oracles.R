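# Exhaustive local-alignment oracle: enumerate every monotone set of aligned
# residue pairs; internal gaps between consecutive pairs are charged
# open + length * extend per gap run, leading/trailing residues are free
# (local alignment), and the empty alignment scores 0.

monotone_matchings <- function(la, lb) {
  out <- list()
  for (k in seq_len(min(la, lb))) {
    ca <- utils::combn(la, k)
    cb <- utils::combn(lb, k)
    for (i in seq_len(ncol(ca))) {
      for (j in seq_len(ncol(cb))) {
        out[[length(out) + 1L]] <- cbind(ca[, i, drop = TRUE], cb[, j, drop = TRUE])
      }
    }
  }
  out
}

# scores for every ordered pair (a in A, b in B); A and B hold sequences of
# one fixed length each
oracle_score_matrix <- function(A, B, S, gap_open, gap_extend) {
  la <- nchar(A[1L]); lb <- nchar(B[1L])
  ms <- monotone_matchings(la, lb)
  gapcost <- vapply(ms, function(m) {
    if (nrow(m) < 2L) return(0)
    p <- diff(m[, 1L]) - 1L
    q <- diff(m[, 2L]) - 1L
    sum((p > 0) * (gap_open + p * gap_extend)) +
      sum((q > 0) * (gap_open + q * gap_extend))
  }, numeric(1))
  sel <- matrix(0, length(ms), la * lb)
  for (t in seq_along(ms)) {
    sel[t, (ms[[t]][, 2L] - 1L) * la + ms[[t]][, 1L]] <- 1
  }
  ae <- do.call(rbind, lapply(strsplit(A, ""), match, table = rownames(S)))
  be <- do.call(rbind, lapply(strsplit(B, ""), match, table = rownames(S)))
  pairs <- expand.grid(a = seq_along(A), b = seq_along(B))
  V <- matrix(0, la * lb, nrow(pairs))
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      V[(j - 1L) * la + i, ] <- S[cbind(ae[pairs$a, i], be[pairs$b, j])]
    }
  }
  sc <- sel %*% V - gapcost
  best <- pmax(0, apply(sc, 2L, max))
  matrix(best, nrow = length(A), ncol = length(B))
}

all_kmers <- function(alphabet, k) {
  apply(expand.grid(rep(list(alphabet), k)), 1L, paste, collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

make_msa <- function(...) {
  rows <- c(...)
  tibble::tibble(id = sprintf("s%02d", seq_along(rows)), aligned = rows)
}

protein_tbl <- function(ids, seqs, genome = NA_character_) {
  tibble::tibble(id = ids, sequence = seqs, genome = genome,
                 subfamily = NA_character_)
}
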