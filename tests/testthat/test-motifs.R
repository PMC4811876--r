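test_that("literal, wildcard and alternative-set patterns locate correctly", {
  hits <- scan_motif("MKRDELLAALGYKV", "DELLA")
  expect_equal(hits$start, 4L)
  expect_equal(hits$end, 8L)
  expect_equal(hits$match_score, 1.0)

  # X positions are unconstrained
  lx <- scan_motif("PPLAALLPP", "LXXLL")
  expect_equal(lx$match_score, 1.0)
  expect_equal(lx$start, 3L)

  # per-position alternative sets: the leading L may be I, V or F
  vr <- scan_motif("AAVRITGAA", "[LIVF]RITG")
  expect_equal(nrow(vr), 1L)
  expect_equal(vr$start, 3L)
  expect_equal(vr$match_score, 1.0)
  expect_equal(nrow(scan_motif("AAKRITGAA", "[LIVF]RITG", min_score = 1)), 0L)

  # pattern longer than the sequence: empty result, not an error
  expect_equal(nrow(scan_motif("ACD", "ACDEFGH")), 0L)
  expect_error(scan_motif("", "ACD"), "empty")
})

test_that("scan keeps non-overlapping windows greedily, best score first", {
  hits <- scan_motif("DELLADELLA", "DELLA")
  expect_equal(hits$start, c(1L, 6L))
  # overlapping equal-score candidates resolve leftmost-first
  hits2 <- scan_motif("AAAAAA", "AAA")
  expect_equal(hits2$start, c(1L, 4L))
  expect_equal(nrow(scan_motif("AAAA", "AAA")), 1L)
})

test_that("conserved windows respect both inclusive bounds and are maximal", {
  # 12 identical columns in 4 rows: one window, per-column identity 1
  m <- make_msa(rep(strrep("K", 12), 4))
  w <- discover_conserved_windows(m, min_identity = 0.5, min_length = 10)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(1L, 12L))
  expect_true(all(w$identities[[1L]] == 1))

  # a 10-column run at exactly 50% column identity is reported ("at least")
  m2 <- make_msa(strrep("K", 10), strrep("K", 10),
                 strrep("A", 10), strrep("C", 10))
  w2 <- discover_conserved_windows(m2, min_identity = 0.5, min_length = 10)
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$identities[[1L]], rep(0.5, 10))

  # 9 perfectly conserved columns flanked by noise stay unreported
  m3 <- make_msa(paste0("A", strrep("K", 9), "C"),
                 paste0("R", strrep("K", 9), "D"),
                 paste0("N", strrep("K", 9), "E"),
                 paste0("D", strrep("K", 9), "F"))
  expect_equal(nrow(discover_conserved_windows(m3, 0.5, 10)), 0L)

  # gaps count against column identity
  m4 <- make_msa(strrep("K", 10), strrep("K", 10), strrep("-", 10), strrep("-", 10))
  expect_equal(nrow(discover_conserved_windows(m4, 0.6, 10)), 0L)
})

test_that("window discovery is invariant to row order and windows are maximal", {
  set.seed(17)
  conserved <- strrep("W", 14)
  rows <- vapply(1:5, function(i)
    paste0(random_protein(11), conserved, random_protein(9)), character(1))
  m <- tibble::tibble(id = sprintf("r%d", 1:5), aligned = rows)
  w <- discover_conserved_windows(m, 0.9, 10)
  perm <- m[c(3, 5, 1, 4, 2), ]
  expect_equal(discover_conserved_windows(perm, 0.9, 10), w)
  expect_true(nrow(w) >= 1L)
  chars <- do.call(rbind, strsplit(m$aligned, ""))
  ident <- apply(chars, 2L,
                 function(col) max(table(col[col != "-"]), 0) / length(col))
  for (k in seq_len(nrow(w))) {
    if (w$start[k] > 1L) expect_lt(ident[w$start[k] - 1L], 0.9)
    if (w$end[k] < length(ident)) expect_lt(ident[w$end[k] + 1L], 0.9)
  }
})

test_that("full-length synthetic GRAS proteins carry all five core motifs in order", {
  sim <- small_sim()
  prot <- sim$genome1[1L, ]
  ann <- annotate_motifs(prot)
  core <- c("LHRI", "VHIID", "LHRII", "PFYRE", "SAW")
  expect_true(all(core %in% ann$hits$motif))
  expect_length(ann$out_of_order, 0L)
  expect_false(any(core %in% ann$missing_expected))
  starts <- ann$hits$start[match(core, ann$hits$motif)]
  expect_true(all(diff(starts) > 0))
})

test_that("truncation before PFYRE flags the downstream core motifs as missing", {
  sim <- small_sim()
  prot <- sim$genome1[1L, ]
  pf <- sim$truth$motifs |>
    dplyr::filter(id == prot$id, motif == "PFYRE")
  truncated <- prot
  truncated$sequence <- substr(prot$sequence, 1L, pf$start - 1L)
  ann <- annotate_motifs(truncated)
  expect_true(all(c("PFYRE", "SAW") %in% ann$missing_expected))
})

test_that("HAM-like proteins built without RVER report it missing", {
  cfg <- simulation_config(seed = 55L, n_subfamilies = 8L,
                           members_per_subfamily = 2L,
                           protein_length = c(320L, 380L),
                           n_tandem_arrays = 0L, n_segmental_pairs = 0L,
                           module_size = 4L)
  sim <- simulate_family(cfg)
  ham_ids <- gv_subfamilies(sim) |> dplyr::filter(subfamily == "HAM")
  expect_gt(nrow(ham_ids), 0L)
  prot <- sim$genome1[sim$genome1$id == ham_ids$id[1L], ]
  ann <- annotate_motifs(prot)
  expect_true("RVER" %in% ann$missing_expected)
})

test_that("motifs planted by the generator are recovered at exact boundaries", {
  sim <- small_sim()
  catalog <- read_motif_catalog()
  proteins <- dplyr::bind_rows(sim$genome1, sim$genome2)
  truth <- sim$truth$motifs
  hit_exact <- vapply(seq_len(nrow(truth)), function(k) {
    prot <- proteins[proteins$id == truth$id[k], ]
    pattern <- catalog$pattern[catalog$name == truth$motif[k]]
    hits <- scan_motif(prot, pattern, motif_name = truth$motif[k])
    any(hits$start == truth$start[k] & hits$end == truth$end[k])
  }, logical(1))
  expect_true(all(hit_exact))
})

test_that("planted windows are rediscovered in the within-subfamily alignment", {
  sim <- small_sim()
  subf <- gv_subfamilies(sim)
  ids <- subf$id[subf$subfamily == subf$subfamily[1L]]
  members <- sim$genome1[sim$genome1$id %in% ids, ]
  msa <- progressive_msa(members)
  w <- discover_conserved_windows(msa, 0.5, 10)
  # every planted motif of at least 10 columns falls inside a reported window
  planted <- sim$truth$motifs |>
    dplyr::filter(id == ids[1L], end - start + 1L >= 10L)
  # the generator plants without indels, so alignment and sequence coordinates
  # coincide for equal-length members
  for (k in seq_len(nrow(planted))) {
    expect_true(any(w$start <= planted$start[k] & w$end >= planted$end[k]))
  }
})
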