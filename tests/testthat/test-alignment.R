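test_that("self-alignment is perfect identity with the diagonal score sum", {
  s <- "MKRDELLAALGYKV"
  hit <- align_local(s, s)
  S <- default_substitution_matrix()
  chars <- strsplit(s, "")[[1L]]
  expect_equal(hit$raw_score, sum(S[cbind(chars, chars)]))
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$q_start, 1L)
  expect_equal(hit$q_end, nchar(s))
})

test_that("uniformly negative cross-scores floor at score 0 with an empty span", {
  hit <- align_local(strrep("W", 12), strrep("P", 12))
  expect_equal(hit$raw_score, 0)
  expect_equal(hit$n_columns, 0L)
  expect_equal(hit$q_start, 0L)
  expect_true(is.nan(hit$identity))
})

test_that("empty sequences are rejected", {
  expect_error(align_local("", "ACD"), "empty")
  expect_error(align_score_matrix("", "ACD"), "empty")
})

test_that("scores equal the exhaustive alignment-enumeration oracle on short words", {
  params <- alignment_params()
  S <- params$substitution_matrix
  alph <- c("A", "R", "N")
  for (la in 1:3) {
    for (lb in 1:3) {
      A <- all_kmers(alph, la)
      B <- all_kmers(alph, lb)
      expect_equal(unname(align_score_matrix(A, B, params)),
                   oracle_score_matrix(A, B, S, params$gap_open,
                                       params$gap_extend),
                   info = sprintf("lengths %d x %d", la, lb))
    }
  }
})

test_that("alignment score is symmetric and monotone under shared suffixes", {
  set.seed(11)
  seqs <- replicate(6, random_protein(40))
  sm <- align_score_matrix(seqs, seqs)
  expect_equal(sm, t(sm))
  for (i in 1:5) {
    a <- random_protein(30)
    suffix <- random_protein(10)
    expect_gte(align_local(paste0(a, suffix), paste0(a, suffix))$raw_score,
               align_local(a, a)$raw_score)
  }
})

test_that("expectation values follow the Karlin-Altschul closed form", {
  p <- alignment_params()
  expect_equal(evalue_ka(0, 100, 1000, p), p$kappa * 100 * 1000)
  # linear in database size, strictly decreasing in score
  expect_equal(evalue_ka(50, 100, 2000, p), 2 * evalue_ka(50, 100, 1000, p))
  expect_lt(evalue_ka(51, 100, 1000, p), evalue_ka(50, 100, 1000, p))
  # frozen regression constant, computed once from kappa*m*n*exp(-lambda*S)
  expect_equal(evalue_ka(200, 500, 1e6, p), 1.3195581319e-16,
               tolerance = 1e-9)
  expect_error(evalue_ka(10, 0, 100, p), "positive")
})

test_that("custom score matrices load from NCBI-format text", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# toy matrix", "   A  R  N", "A  2 -1 -1", "R -1  2 -1",
               "N -1 -1  2"), path)
  S <- read_score_matrix(path)
  expect_equal(dim(S), c(3L, 3L))
  expect_equal(S["A", "A"], 2)
  expect_equal(S["A", "R"], -1)
})

test_that("identical sequences align without gaps and in input order", {
  recs <- protein_tbl(c("a", "b", "c"), rep("MKRDELLAALGYKV", 3))
  m <- progressive_msa(recs)
  expect_equal(m$id, recs$id)
  expect_false(any(grepl("-", m$aligned, fixed = TRUE)))
  expect_equal(nchar(m$aligned[1L]), 14L)
})

test_that("two sequences reduce to the global end-gap-free pairwise alignment", {
  recs <- protein_tbl(c("a", "b"), c("MKRDELLAALGYKV", "MKRDELLAGYKV"))
  m <- progressive_msa(recs)
  expect_equal(nchar(m$aligned[1L]), 14L)
  expect_equal(gsub("-", "", m$aligned[1L]), recs$sequence[1L])
  expect_equal(gsub("-", "", m$aligned[2L]), recs$sequence[2L])
})

test_that("degapping reproduces the inputs and columns bound the longest input", {
  set.seed(5)
  base <- random_protein(60)
  recs <- protein_tbl(sprintf("m%d", 1:4), c(
    base,
    paste0(substr(base, 1, 30), substr(base, 36, 60)),
    paste0("AC", base),
    substr(base, 5, 60)
  ))
  m <- progressive_msa(recs)
  expect_equal(gsub("-", "", m$aligned), recs$sequence)
  expect_gte(nchar(m$aligned[1L]), max(nchar(recs$sequence)))
  expect_error(progressive_msa(recs[1, ]), "at least 2")
})

test_that("column masking removes strictly below the coverage floor", {
  # 20 rows x 4 columns; column 2 carries exactly one gap (coverage 0.95,
  # kept: removal is strict "less than") and column 3 is all gaps (removed)
  m <- make_msa(c("A--D", rep("AC-D", 19L)))
  masked <- mask_columns(m, 0.95)
  expect_equal(nchar(masked$aligned[1L]), 3L)
  expect_equal(masked$aligned[1L], "A-D")
  expect_equal(masked$aligned[2L], "ACD")

  # gap-free alignment is unchanged
  clean <- make_msa(rep("ACDEF", 4))
  expect_equal(mask_columns(clean, 0.95), clean)

  # removing every column is an error
  allgap <- make_msa("---", "A--")
  expect_error(mask_columns(allgap, 0.95), "every alignment column")
})
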