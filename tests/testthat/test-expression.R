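# two genes with an exact target Pearson correlation across n conditions
profiles_with_pcc <- function(rho, n = 24L, center = 6) {
  x <- scale(seq_len(n))[, 1L]
  e <- scale(stats::residuals(stats::lm(rnorm(n) ~ x)))[, 1L]
  y <- rho * x + sqrt(1 - rho^2) * e
  list(a = center + x, b = center + y)
}

# gene x condition tibble from a named-row matrix
avg_from_matrix <- function(mat) {
  colnames(mat) <- sprintf("c%02d", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(gene = rownames(mat)),
                   tibble::as_tibble(as.data.frame(mat)))
}

test_that("replicate averaging is the arithmetic mean in log2 space", {
  expr <- tibble::tibble(gene = c("g1", "g2"),
                         s1 = c(8, 7), s2 = c(8, 9),
                         s3 = c(8, 7), s4 = c(8, 9))
  design <- tibble::tibble(sample = c("s1", "s2", "s3", "s4"),
                           condition = c("c1", "c1", "c1", "c1"),
                           tissue = "leaf", po_id = "PO:0000001",
                           platform = "chip")
  avg <- average_replicates(expr, design)
  expect_equal(avg$c1, c(8, 8))

  design2 <- design
  design2$condition <- c("c1", "c1", "c2", "c2")
  avg2 <- average_replicates(expr, design2)
  expect_equal(avg2$c1, c(8, 8))
  expect_equal(avg2$c2, c(8, 8))

  expect_error(average_replicates(expr, design[1:3, ]), "without a condition")
})

test_that("mixed 3- and 4-replicate designs collapse to one column per condition", {
  sim <- small_sim()
  se <- simulate_expression(small_config(), sim$genome1$id)
  reps <- table(se$design$condition)
  expect_true(all(reps %in% c(3L, 4L)))
  avg <- average_replicates(se$expr, se$design)
  expect_equal(ncol(avg) - 1L, dplyr::n_distinct(se$design$condition))
  expect_equal(nrow(attr(avg, "conditions")),
               dplyr::n_distinct(se$design$condition))
})

test_that("tissue attribution is inclusive at the threshold and monotone", {
  avg <- tibble::tibble(gene = c("high", "edge", "low"),
                        c1 = c(8.3, 8.0, 7.9), c2 = c(5, 5, 7.9))
  conds <- tibble::tibble(condition = c("c1", "c2"),
                          tissue = c("leaf", "root"),
                          po_id = c("PO:0000001", "PO:0000002"),
                          platform = "chip")
  attr(avg, "conditions") <- conds
  po <- po_attribution(avg, threshold = 8)
  expect_setequal(po$gene, c("high", "edge"))
  expect_equal(sort(unique(po$tissue)), "leaf")
  # exactly 8.0 attributed under the inclusive default, dropped when strict
  expect_false("edge" %in% po_attribution(avg, threshold = 8,
                                          inclusive = FALSE)$gene)
  # raising the threshold never adds attributions
  po9 <- po_attribution(avg, threshold = 9)
  expect_true(all(paste(po9$gene, po9$po_id) %in% paste(po$gene, po$po_id)))
})

test_that("identical profiles co-cluster at distance zero", {
  set.seed(2)
  x <- rnorm(12, 6)
  avg <- avg_from_matrix(rbind(a = x, b = x, noise = rnorm(12, 6)))
  cl <- coexpression_clusters(avg)
  expect_equal(cl$cluster[cl$gene == "a"], cl$cluster[cl$gene == "b"])
  expect_false(is.na(cl$cluster[cl$gene == "a"]))
  D <- attr(cl, "distances")
  expect_equal(unname(D["a", "b"]), 0)
})

test_that("a pair at correlation 0.75 is never co-clustered at the 0.2 cutoff", {
  set.seed(4)
  p <- profiles_with_pcc(0.75)
  avg <- avg_from_matrix(rbind(a = p$a, b = p$b))
  cl <- coexpression_clusters(avg, cutoff = 0.2)
  expect_equal(unname(attr(cl, "distances")["a", "b"]), 0.25, tolerance = 1e-10)
  expect_true(all(is.na(cl$cluster)))
})

test_that("a pair at distance exactly the cutoff stays apart (strict bound)", {
  set.seed(6)
  p <- profiles_with_pcc(0.8)
  avg <- avg_from_matrix(rbind(a = p$a, b = p$b))
  cl <- coexpression_clusters(avg, cutoff = 0.2)
  expect_equal(unname(attr(cl, "distances")["a", "b"]), 0.2, tolerance = 1e-12)
  expect_true(all(is.na(cl$cluster)))
})

test_that("constant profiles are excluded with a warning", {
  avg <- tibble::tibble(gene = c("flat", "a", "b"),
                        c1 = c(5, 6, 6.1), c2 = c(5, 7, 7.2), c3 = c(5, 8, 8.1))
  expect_warning(cl <- coexpression_clusters(avg), "constant")
  expect_true(is.na(cl$cluster[cl$gene == "flat"]))
  expect_error(coexpression_clusters(avg[, 1:2]), "at least 2 conditions")
})

test_that("every within-cluster pair respects the strict distance bound", {
  sim <- small_sim()
  se <- simulate_expression(small_config(), sim$genome1$id)
  avg <- average_replicates(se$expr, se$design)
  cl <- coexpression_clusters(avg, cutoff = 0.2)
  D <- attr(cl, "distances")
  for (g in unique(stats::na.omit(cl$cluster))) {
    members <- cl$gene[!is.na(cl$cluster) & cl$cluster == g]
    expect_gte(length(members), 2L)
    expect_lt(max(D[members, members]), 0.2)
  }
})

test_that("the planted co-expression module is recovered intact", {
  sim <- small_sim()
  se <- simulate_expression(small_config(), sim$genome1$id)
  avg <- average_replicates(se$expr, se$design)
  cl <- coexpression_clusters(avg, cutoff = 0.2)
  mod <- se$truth$module_genes
  ids <- cl$cluster[match(mod, cl$gene)]
  expect_false(anyNA(ids))
  expect_equal(dplyr::n_distinct(ids), 1L)
  # and nothing else joins the module cluster
  expect_setequal(cl$gene[!is.na(cl$cluster) & cl$cluster == ids[1L]], mod)
  # partner lists follow from the clusters and are symmetric
  p1 <- coexpression_partners(cl, mod[1L])
  expect_setequal(p1, setdiff(mod, mod[1L]))
  expect_true(mod[1L] %in% coexpression_partners(cl, mod[2L]))
  unclustered <- cl$gene[is.na(cl$cluster)][1L]
  expect_equal(coexpression_partners(cl, unclustered), character(0))
  expect_error(coexpression_partners(cl, "no_such_gene"), "unknown gene")
})

test_that("boosted genes gain the PO term of their designated tissue", {
  sim <- small_sim()
  se <- simulate_expression(small_config(), sim$genome1$id)
  avg <- average_replicates(se$expr, se$design)
  po <- po_attribution(avg)
  ts <- se$truth$tissue_specific
  hit <- paste(ts$gene, ts$po_id) %in% paste(po$gene, po$po_id)
  expect_true(all(hit))
})
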