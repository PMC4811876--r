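test_that("p-distances count mismatches over mutually ungapped columns", {
  m <- make_msa("ACDEFGHIKL", "ACDEFGHIKL")
  d <- msa_distances(m, "p_distance")
  expect_equal(unname(d[1L, 2L]), 0)

  # 10 columns, 3 mismatches among mutually ungapped columns
  m2 <- make_msa("ACDEFGHIKL", "ACDEFGHWYV")
  expect_equal(unname(msa_distances(m2, "p_distance")[1L, 2L]), 0.3)

  # gapped columns do not enter the denominator
  m3 <- make_msa("AC--FGHIKL", "ACDE--HWKL")
  expect_equal(unname(msa_distances(m3, "p_distance")[1L, 2L]), 1 / 6)

  expect_error(msa_distances(make_msa("AC--", "--DE"), "p_distance"),
               "no mutually ungapped")
})

test_that("the corrected distance is never below the raw mismatch fraction", {
  set.seed(9)
  for (i in 1:10) {
    rows <- replicate(4, random_protein(60))
    m <- tibble::tibble(id = sprintf("r%d", 1:4), aligned = rows)
    p <- msa_distances(m, "p_distance")
    j <- msa_distances(m, "jtt_corrected")
    expect_true(all(j >= p - 1e-12))
  }
})

test_that("the three-taxon tree solves in closed form", {
  d <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2L])], tr$tip.label)
  expect_equal(unname(lens["A"]), 1)
  expect_equal(unname(lens["B"]), 1)
  expect_equal(unname(lens["C"]), 3)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("additive matrices are recovered exactly, topology and branch lengths", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:6, 1L)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(ref)
    tr <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), tr)), 0)
    back <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(back, d, tolerance = 1e-8)
  }
})

test_that("an ultrametric four-taxon matrix matches single-linkage grouping", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.2
  tr <- nj_tree(d)
  sl <- cutree(hclust(as.dist(d), method = "single"), k = 2)
  # NJ recovers the split {A,B} | {C,D} that single linkage finds
  parts <- ape::prop.part(tr)
  sides <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(any(vapply(sides, identical, logical(1), y = c("A", "B"))) ||
                any(vapply(sides, identical, logical(1), y = c("C", "D"))))
  expect_equal(sort(names(sl[sl == sl["A"]])), c("A", "B"))
})

test_that("a uniformly supported split appears at support 100", {
  m <- make_msa(strrep("A", 30), strrep("A", 30), strrep("C", 30), strrep("C", 30))
  tr <- bootstrap_consensus(m, phylo_params(bootstrap_replicates = 25, seed = 4,
                                            distance_model = "p_distance"))
  expect_equal(attr(tr, "n_replicates_used"), 25L)
  expect_true("100" %in% tr$node.label)
  parts <- ape::prop.part(tr)
  sides <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(any(vapply(sides, identical, logical(1), y = c("s01", "s02"))) ||
                any(vapply(sides, identical, logical(1), y = c("s03", "s04"))))
})

test_that("bootstrap consensus is seed-deterministic and leaf-order invariant", {
  set.seed(31)
  base <- random_protein(50)
  rows <- vapply(1:6, function(i) {
    ch <- strsplit(base, "")[[1L]]
    ch[sample(50, 8)] <- "A"
    paste(ch, collapse = "")
  }, character(1))
  m <- tibble::tibble(id = sprintf("t%d", 1:6), aligned = rows)
  pp <- phylo_params(bootstrap_replicates = 40, seed = 99,
                     distance_model = "p_distance")
  t1 <- bootstrap_consensus(m, pp)
  t2 <- bootstrap_consensus(m, pp)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  perm <- m[c(4, 1, 6, 2, 5, 3), ]
  t3 <- bootstrap_consensus(perm, pp)
  key <- function(tr) {
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    sort(vapply(parts, function(p) paste(sort(labs[p]), collapse = "|"),
                character(1)))
  }
  expect_equal(key(t3), key(t1))
})

test_that("two planted clades survive collapsing at the default support floor", {
  # 2 clades x 4 members, 40 informative columns plus noise
  set.seed(77)
  cladeA <- random_protein(40)
  cladeB <- random_protein(40)
  noise <- function() random_protein(20)
  rows <- c(vapply(1:4, function(i) paste0(cladeA, noise()), character(1)),
            vapply(1:4, function(i) paste0(cladeB, noise()), character(1)))
  m <- tibble::tibble(id = sprintf("g%d", 1:8), aligned = rows)
  tr <- bootstrap_consensus(m, phylo_params(bootstrap_replicates = 100, seed = 13,
                                            distance_model = "p_distance"))
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  sides <- lapply(parts, function(p) sort(labs[p]))
  has_clade <- function(members) {
    any(vapply(sides, identical, logical(1), y = sort(members))) ||
      any(vapply(sides, function(s) identical(sort(setdiff(labs, s)),
                                              sort(members)), logical(1)))
  }
  expect_true(has_clade(sprintf("g%d", 1:4)))
  expect_true(has_clade(sprintf("g%d", 5:8)))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] >= 30))
})

test_that("subfamily labels propagate from anchors through retained clades", {
  # star tree: nothing is assignable
  star <- ape::read.tree(text = "(a,b,c,anchor1);")
  asg <- assign_subfamilies(star, c(anchor1 = "DELLA"))
  expect_true(all(is.na(asg$subfamily[!asg$is_anchor])))

  # a supported clade {anchor, x, y} labels its members
  tr <- ape::read.tree(text = "((anchor1,x,y)80,(z,w));")
  asg <- assign_subfamilies(tr, c(anchor1 = "DELLA"))
  expect_equal(asg$subfamily[asg$id %in% c("x", "y")], c("DELLA", "DELLA"))
  expect_true(is.na(asg$subfamily[asg$id == "z"]))

  # mixed-anchor clades leave leaves unassigned
  tr2 <- ape::read.tree(text = "((anchor1,anchor2,x),(z,w));")
  asg2 <- assign_subfamilies(tr2, c(anchor1 = "DELLA", anchor2 = "HAM"))
  expect_true(is.na(asg2$subfamily[asg2$id == "x"]))

  expect_error(assign_subfamilies(star, c(ghost = "PAT")), "missing from tree")
})

test_that("a full synthetic family is assigned to its subfamilies without error", {
  sim <- small_sim()
  msa <- progressive_msa(sim$genome1)
  masked <- mask_columns(msa)
  tr <- bootstrap_consensus(masked, phylo_params(bootstrap_replicates = 50,
                                                 seed = 8))
  asg <- assign_subfamilies(tr, truth_anchors(sim))
  cmp <- dplyr::inner_join(asg, gv_subfamilies(sim), by = "id")
  expect_equal(mean(cmp$subfamily.x == cmp$subfamily.y), 1.0)
})
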