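#' Synthetic gene-family simulation settings
#'
#' The generator emulates the shape of a plant GRAS-type transcription-factor
#' family: subfamily-structured proteins of 400-700 residues with motifs
#' planted at fixed offsets (exactly conserved within their subfamilies),
#' tandem arrays and segmental paralog pairs laid out on simulated
#' chromosomes, a second genome of orthologs at controlled divergence with a
#' fraction of subfamilies lost, and an expression atlas with replicated
#' conditions, tissue-specific highs and a correlated co-expression module.
#' Defaults mirror a 13-subfamily, 52-gene family. Divergences are expected
#' substitutions per site; sequence evolution is residue-frequency-weighted
#' random replacement along star-like subfamily trees (no indels), which is
#' sufficient for stages that consume identities and distances rather than
#' model fits.
#'
#' @param seed Integer seed; the same seed reproduces every output byte for
#'   byte.
#' @param n_subfamilies Number of subfamilies (default 13).
#' @param members_per_subfamily Members per subfamily (default 4).
#' @param protein_length Length range in residues, drawn per subfamily
#'   (default 400-700).
#' @param within_subfamily_divergence,between_subfamily_divergence Expected
#'   substitutions/site within a subfamily and between subfamily ancestors;
#'   within must be smaller.
#' @param ortholog_divergence Substitutions/site separating each second-genome
#'   ortholog from its first-genome counterpart (default 0.1).
#' @param n_tandem_arrays Subfamilies laid out as tandem arrays (default 2).
#' @param n_segmental_pairs Subfamilies contributing a segmental paralog pair
#'   (default 3).
#' @param lost_subfamily_fraction Fraction of subfamilies absent from the
#'   second genome (default 0.25), emulating lineage-specific loss.
#' @param n_lineage_duplicates Extra near-identical duplicates planted in the
#'   second genome (default 0).
#' @param planted_motifs Tibble `name`, `pattern`, `subfamily` of motifs to
#'   plant; `NULL` uses the bundled catalog with its subfamily conventions
#'   (core motifs everywhere, RVER absent from HAM, DELLA/TVHYNP in DELLA,
#'   XIV/XV in HAM, XVI in PAT).
#' @param expr_n_conditions Conditions in the simulated atlas (default 50).
#' @param module_size,module_pcc Size and target pairwise Pearson correlation
#'   of the planted co-expression module (defaults 10 and 0.9).
#' @param n_tissue_specific Genes boosted above the attribution threshold in
#'   one designated tissue (default 6).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_subfamilies = 13L,
                              members_per_subfamily = 4L,
                              protein_length = c(400L, 700L),
                              within_subfamily_divergence = 0.1,
                              between_subfamily_divergence = 0.8,
                              ortholog_divergence = 0.1,
                              n_tandem_arrays = 2L,
                              n_segmental_pairs = 3L,
                              lost_subfamily_fraction = 0.25,
                              n_lineage_duplicates = 0L,
                              planted_motifs = NULL,
                              expr_n_conditions = 50L,
                              module_size = 10L,
                              module_pcc = 0.9,
                              n_tissue_specific = 6L) {
  cfg <- list(seed = as.integer(seed),
              n_subfamilies = as.integer(n_subfamilies),
              members_per_subfamily = as.integer(members_per_subfamily),
              protein_length = as.integer(protein_length),
              within_subfamily_divergence = within_subfamily_divergence,
              between_subfamily_divergence = between_subfamily_divergence,
              ortholog_divergence = ortholog_divergence,
              n_tandem_arrays = as.integer(n_tandem_arrays),
              n_segmental_pairs = as.integer(n_segmental_pairs),
              lost_subfamily_fraction = lost_subfamily_fraction,
              n_lineage_duplicates = as.integer(n_lineage_duplicates),
              planted_motifs = planted_motifs,
              expr_n_conditions = as.integer(expr_n_conditions),
              module_size = as.integer(module_size),
              module_pcc = module_pcc,
              n_tissue_specific = as.integer(n_tissue_specific))
  if (cfg$within_subfamily_divergence < 0 || cfg$between_subfamily_divergence < 0 ||
      cfg$ortholog_divergence < 0) {
    abort("divergences must be non-negative")
  }
  if (cfg$within_subfamily_divergence >= cfg$between_subfamily_divergence) {
    abort("within-subfamily divergence must be below between-subfamily divergence")
  }
  if (cfg$n_tandem_arrays + cfg$n_segmental_pairs > cfg$n_subfamilies) {
    abort("infeasible layout: more tandem arrays plus segmental pairs than subfamilies")
  }
  if (cfg$n_tandem_arrays > 0L && cfg$members_per_subfamily < 2L) {
    abort("infeasible layout: tandem arrays need at least 2 members per subfamily")
  }
  if (cfg$n_segmental_pairs > 0L && cfg$members_per_subfamily < 2L) {
    abort("infeasible layout: segmental pairs need at least 2 members per subfamily")
  }
  if (cfg$module_size > cfg$n_subfamilies * cfg$members_per_subfamily) {
    abort("module_size exceeds the number of genes")
  }
  structure(cfg, class = "simulation_config")
}

# amino-acid background frequencies (Robinson-Robinson style)
aa_background <- c(
  A = 0.079, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.068, T = 0.059, W = 0.014,
  Y = 0.032, V = 0.065
)

subfamily_names <- function(n) {
  canon <- c("LISCL", "PAT", "SHR", "DELLA", "SCR", "SCL3", "LAS", "HAM",
             "SCL26", "GRAS8", "GRASV1", "GRASV2", "GRASV3")
  if (n <= length(canon)) canon[seq_len(n)]
  else c(canon, sprintf("SF%02d", seq_len(n - length(canon))))
}

member_symbols <- function(subfamily, k) {
  if (grepl("[0-9]$", subfamily)) paste0(subfamily, letters[seq_len(k)])
  else paste0(subfamily, seq_len(k))
}

random_protein_chars <- function(L) {
  sample(names(aa_background), L, replace = TRUE, prob = aa_background)
}

# substitute each site with probability 1 - exp(-d); replacements drawn from
# the background excluding the current residue
mutate_chars <- function(chars, d) {
  if (d <= 0) return(chars)
  q <- 1 - exp(-d)
  hit <- which(runif(length(chars)) < q)
  for (i in hit) {
    p <- aa_background
    p[chars[i]] <- 0
    chars[i] <- sample(names(p), 1L, prob = p)
  }
  chars
}

# Concrete instance of a pattern. Wildcard positions draw from the
# background excluding the pattern's own specified residues, and the
# instance carries a neutral 3-residue guard flank, so a planted instance
# matches its pattern at exactly one window and ground-truth boundaries are
# unambiguous.
instantiate_pattern <- function(pattern) {
  comp <- compile_pattern(pattern)
  specified <- unique(unlist(comp[!vapply(comp, is.null, logical(1))]))
  pool <- aa_background[setdiff(names(aa_background), specified)]
  chars <- vapply(comp, function(pos) {
    if (is.null(pos)) sample(names(pool), 1L, prob = pool)
    else pos[1L]
  }, character(1))
  list(chars = chars, guard = names(pool)[1L])
}

plant_instance <- function(chars, start, instance) {
  idx <- start + seq_along(instance$chars) - 1L
  chars[idx] <- instance$chars
  guard_idx <- c(seq(start - 3L, start - 1L),
                 seq(max(idx) + 1L, max(idx) + 3L))
  guard_idx <- guard_idx[guard_idx >= 1L & guard_idx <= length(chars)]
  chars[guard_idx] <- instance$guard
  chars
}

default_planted_motifs <- function(subfams) {
  cat <- read_motif_catalog()
  rule <- function(name) {
    switch(name,
           RVER = setdiff(subfams, "HAM"),
           DELLA = intersect(subfams, "DELLA"),
           TVHYNP = intersect(subfams, "DELLA"),
           XIV = intersect(subfams, "HAM"),
           XV = intersect(subfams, "HAM"),
           XVI = intersect(subfams, "PAT"),
           `VHIID-C` = subfams,
           LXXLL = subfams,
           subfams)
  }
  purrr::pmap_dfr(cat, function(name, region, pattern) {
    tibble::tibble(name = name, region = region, pattern = pattern,
                   subfamily = rule(name))
  })
}

# fixed in-sequence offsets for a subfamily's planted motifs: N-terminal
# units near the start, GRAS-domain units in the C-terminal half
motif_offsets <- function(planted, L) {
  pos_n <- 6L
  pos_c <- as.integer(floor(L * 0.45))
  starts <- integer(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    w <- nchar(planted$pattern_width_proxy[i])
    if (planted$region[i] == "N_terminal") {
      starts[i] <- pos_n
      pos_n <- pos_n + w + 8L
    } else {
      starts[i] <- pos_c
      pos_c <- pos_c + w + 12L
    }
  }
  if (pos_c - 1L > L || pos_n > as.integer(floor(L * 0.45))) {
    abort("infeasible config: planted motifs do not fit in the protein length")
  }
  starts
}

#' Simulate a two-genome gene family with ground truth
#'
#' See [simulation_config()] for what is emulated. Returns in-memory tibbles
#' plus a ground-truth list; [write_simulation()] serializes the same
#' objects to files, byte-identically for a fixed seed.
#'
#' @param config A [simulation_config()] object.
#' @return A list: `genome1` and `genome2` ([protein_records] tibbles,
#'   genome labels `"GV"` and `"GX"`), `loci` (a [locus_table] for genome 1),
#'   `segment_map`, `truth` (subfamilies, orthologs, motifs, tandem,
#'   segmental, lost subfamilies), and `config`.
#' @export
simulate_family <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ns <- config$n_subfamilies
  k <- config$members_per_subfamily
  subfams <- subfamily_names(ns)
  planted_all <- config$planted_motifs
  if (is.null(planted_all)) planted_all <- default_planted_motifs(subfams)

  # subfamily ancestors: a shared root mutated at half the between-subfamily
  # divergence on each ancestor branch
  Lmax <- max(config$protein_length)
  root <- random_protein_chars(Lmax)
  lens <- sample(seq(min(config$protein_length), max(config$protein_length)),
                 ns, replace = TRUE)

  tandem_subs <- if (config$n_tandem_arrays > 0L) subfams[seq_len(config$n_tandem_arrays)] else character(0)
  seg_subs <- if (config$n_segmental_pairs > 0L) {
    subfams[config$n_tandem_arrays + seq_len(config$n_segmental_pairs)]
  } else character(0)
  n_lost <- round(config$lost_subfamily_fraction * ns)
  lost_subs <- if (n_lost > 0L) utils::tail(subfams, n_lost) else character(0)

  genome1 <- list(); loci_rows <- list(); motif_rows <- list()
  truth_sub <- list(); ortho_rows <- list(); genome2 <- list()
  tandem_rows <- list(); seg_rows <- list(); map_rows <- list()
  locus_counter <- integer(19)

  new_locus_id <- function(chrom) {
    locus_counter[chrom] <<- locus_counter[chrom] + 1L
    sprintf("Synt%02dg%05d", chrom, locus_counter[chrom] * 10L)
  }

  for (s in seq_len(ns)) {
    sf <- subfams[s]
    L <- lens[s]
    ancestor <- mutate_chars(root[seq_len(L)],
                             config$between_subfamily_divergence / 2)
    planted <- planted_all[planted_all$subfamily == sf, , drop = FALSE]
    planted$pattern_width_proxy <- vapply(planted$pattern, function(p)
      paste(rep("x", length(compile_pattern(p))), collapse = ""), character(1))
    starts <- if (nrow(planted) > 0L) motif_offsets(planted, L) else integer(0)
    instances <- lapply(planted$pattern, instantiate_pattern)

    chrom <- ((s - 1L) %% 19L) + 1L
    base <- 1e6 + floor((s - 1L) / 19L) * 5e7
    symbols <- member_symbols(sf, k)
    member_ids <- character(k)

    for (m in seq_len(k)) {
      chars <- mutate_chars(ancestor, config$within_subfamily_divergence / 2)
      for (j in seq_along(instances)) {
        chars <- plant_instance(chars, starts[j], instances[[j]])
      }
      seqn <- paste(chars, collapse = "")

      if (sf %in% tandem_subs) {
        this_chrom <- chrom
        start <- if (m == 1L) base else {
          prev <- loci_rows[[length(loci_rows)]]
          prev$end + sample(10000:20000, 1L)
        }
      } else if (sf %in% seg_subs && m == 2L) {
        this_chrom <- ((chrom + 6L) %% 19L) + 1L
        start <- 2e7 + s * 1e6
      } else {
        this_chrom <- chrom
        start <- base + (m - 1L) * 2e6
      }
      id <- new_locus_id(this_chrom)
      member_ids[m] <- id
      end <- start + 3 * L - 1
      loci_rows[[length(loci_rows) + 1L]] <- tibble::tibble(
        locus_id = id, short_name = symbols[m], chromosome = this_chrom,
        strand = if (m %% 2L == 1L) "+" else "-", exon = 1L,
        start = start, end = end)
      genome1[[length(genome1) + 1L]] <- tibble::tibble(
        id = id, sequence = seqn, genome = "GV", subfamily = NA_character_)
      truth_sub[[length(truth_sub) + 1L]] <- tibble::tibble(
        id = id, genome = "GV", subfamily = sf)
      if (nrow(planted) > 0L) {
        motif_rows[[length(motif_rows) + 1L]] <- tibble::tibble(
          genome = "GV", id = id, motif = planted$name, start = starts,
          end = starts + vapply(instances, function(i) length(i$chars), integer(1)) - 1L)
      }

      if (!sf %in% lost_subs) {
        ochars <- mutate_chars(chars, config$ortholog_divergence)
        for (j in seq_along(instances)) {
          ochars <- plant_instance(ochars, starts[j], instances[[j]])
        }
        oid <- paste0("GX_", symbols[m])
        genome2[[length(genome2) + 1L]] <- tibble::tibble(
          id = oid, sequence = paste(ochars, collapse = ""), genome = "GX",
          subfamily = NA_character_)
        truth_sub[[length(truth_sub) + 1L]] <- tibble::tibble(
          id = oid, genome = "GX", subfamily = sf)
        ortho_rows[[length(ortho_rows) + 1L]] <- tibble::tibble(
          query_id = id, target_id = oid)
        if (nrow(planted) > 0L) {
          motif_rows[[length(motif_rows) + 1L]] <- tibble::tibble(
            genome = "GX", id = oid, motif = planted$name, start = starts,
            end = starts + vapply(instances, function(i) length(i$chars), integer(1)) - 1L)
        }
      }
    }

    if (sf %in% tandem_subs) {
      tandem_rows[[length(tandem_rows) + 1L]] <- tibble::tibble(
        array = length(tandem_rows) + 1L, subfamily = sf, locus_id = member_ids)
    }
    if (sf %in% seg_subs) {
      rows <- dplyr::bind_rows(loci_rows)
      span1 <- rows[rows$locus_id == member_ids[1L], ]
      span2 <- rows[rows$locus_id == member_ids[2L], ]
      map_rows[[length(map_rows) + 1L]] <- tibble::tibble(
        chrom_a = span1$chromosome, start_a = span1$start - 5e4,
        end_a = span1$end + 5e4,
        chrom_b = span2$chromosome, start_b = span2$start - 5e4,
        end_b = span2$end + 5e4)
      seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
        pair = length(seg_rows) + 1L, subfamily = sf,
        locus_a = member_ids[1L], locus_b = member_ids[2L])
    }
  }

  genome2_tbl <- dplyr::bind_rows(genome2)
  if (config$n_lineage_duplicates > 0L) {
    nd <- min(config$n_lineage_duplicates, nrow(genome2_tbl))
    for (i in seq_len(nd)) {
      src <- genome2_tbl[i, ]
      dup_chars <- mutate_chars(strsplit(src$sequence, "")[[1L]], 0.05)
      genome2_tbl <- dplyr::bind_rows(genome2_tbl, tibble::tibble(
        id = paste0(src$id, "_dup"),
        sequence = paste(dup_chars, collapse = ""),
        genome = "GX", subfamily = NA_character_))
    }
  }

  list(
    genome1 = dplyr::bind_rows(genome1),
    genome2 = genome2_tbl,
    loci = validate_locus_table(dplyr::bind_rows(loci_rows)),
    segment_map = if (length(map_rows) > 0L) dplyr::bind_rows(map_rows) else
      tibble::tibble(chrom_a = integer(), start_a = numeric(), end_a = numeric(),
                     chrom_b = integer(), start_b = numeric(), end_b = numeric()),
    truth = list(
      subfamilies = dplyr::bind_rows(truth_sub),
      orthologs = dplyr::bind_rows(ortho_rows),
      motifs = dplyr::bind_rows(motif_rows),
      tandem = if (length(tandem_rows) > 0L) dplyr::bind_rows(tandem_rows) else
        tibble::tibble(array = integer(), subfamily = character(), locus_id = character()),
      segmental = if (length(seg_rows) > 0L) dplyr::bind_rows(seg_rows) else
        tibble::tibble(pair = integer(), subfamily = character(),
                       locus_a = character(), locus_b = character()),
      lost_subfamilies = lost_subs
    ),
    config = config
  )
}

tissue_vocabulary <- function() {
  tibble::tibble(
    tissue = c("leaf", "root", "stem", "berry", "flower", "seed", "pollen",
               "tendril", "bud", "rachis"),
    po_id = sprintf("PO:%07d", 9000 + seq_len(10))
  )
}

#' Simulate an expression atlas with planted structure
#'
#' Per-condition means are drawn around a log2 baseline of about 6;
#' module genes share a latent condition factor tuned so that their pairwise
#' Pearson correlation matches `module_pcc`; tissue-specific genes are
#' boosted well above the attribution threshold in the conditions of their
#' designated tissue; each condition carries 3 or 4 replicates with
#' independent noise.
#'
#' @param config A [simulation_config()] object.
#' @param gene_ids Character vector of gene IDs (at least 2 conditions are
#'   required by the config).
#' @return A list: `expr` (gene x sample tibble), `design` (replicate
#'   design), `truth` (`module_genes`, `tissue_specific`).
#' @export
simulate_expression <- function(config = simulation_config(), gene_ids) {
  if (config$expr_n_conditions < 2L) abort("need at least 2 conditions")
  set.seed(config$seed + 1000003L)
  ng <- length(gene_ids)
  nc <- config$expr_n_conditions
  vocab <- tissue_vocabulary()
  cond <- tibble::tibble(
    condition = sprintf("C%03d", seq_len(nc)),
    tissue = vocab$tissue[((seq_len(nc) - 1L) %% nrow(vocab)) + 1L],
    po_id = vocab$po_id[((seq_len(nc) - 1L) %% nrow(vocab)) + 1L],
    platform = "synthetic_array",
    n_reps = 3L + (seq_len(nc) %% 2L)
  )
  module_genes <- gene_ids[seq_len(min(config$module_size, ng))]
  ts_pool <- setdiff(gene_ids, module_genes)
  nts <- min(config$n_tissue_specific, length(ts_pool), nrow(vocab))
  tissue_specific <- tibble::tibble(
    gene = ts_pool[seq_len(nts)],
    tissue = vocab$tissue[seq_len(nts)],
    po_id = vocab$po_id[seq_len(nts)]
  )

  sigma_c <- 0.6   # condition-level idiosyncratic sd (log2 units)
  sigma_r <- 0.2   # replicate noise sd
  b <- sigma_c * sqrt(config$module_pcc / (1 - config$module_pcc))
  mu <- rnorm(ng, mean = 6, sd = 0.3)
  f <- rnorm(nc)   # shared module factor per condition

  cond_means <- matrix(rnorm(ng * nc, sd = sigma_c), ng, nc) + mu
  is_mod <- gene_ids %in% module_genes
  cond_means[is_mod, ] <- cond_means[is_mod, ] + outer(rep(b, sum(is_mod)), f)
  for (i in seq_len(nrow(tissue_specific))) {
    g <- match(tissue_specific$gene[i], gene_ids)
    boost_cols <- cond$tissue == tissue_specific$tissue[i]
    cond_means[g, boost_cols] <- cond_means[g, boost_cols] + 3.5
  }

  sample_names <- unlist(purrr::map2(cond$condition, cond$n_reps,
                                     ~ sprintf("%s_r%d", .x, seq_len(.y))))
  design <- tibble::tibble(
    sample = sample_names,
    condition = rep(cond$condition, cond$n_reps),
    tissue = rep(cond$tissue, cond$n_reps),
    po_id = rep(cond$po_id, cond$n_reps),
    platform = "synthetic_array"
  )
  vals <- matrix(NA_real_, ng, length(sample_names))
  ci <- rep(seq_len(nc), cond$n_reps)
  for (j in seq_along(sample_names)) {
    vals[, j] <- cond_means[, ci[j]] + rnorm(ng, sd = sigma_r)
  }
  expr <- tibble::as_tibble(as.data.frame(vals, col.names = sample_names))
  names(expr) <- sample_names
  expr <- dplyr::bind_cols(tibble::tibble(gene = gene_ids), expr)
  list(expr = expr, design = design,
       truth = list(module_genes = module_genes,
                    tissue_specific = tissue_specific))
}

#' Serialize a simulation to files
#'
#' Writes the two genome FASTAs, the genome-1 locus table and GFF3, the
#' segment map and the ground truth (JSON) into a directory. Outputs are
#' byte-identical across runs with the same config.
#'
#' @param sim A list from [simulate_family()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_fasta(sim$genome1, file.path(dir, "genome1.faa"))
  write_protein_fasta(sim$genome2, file.path(dir, "genome2.faa"))
  write_locus_table(sim$loci, file.path(dir, "loci.tsv"))
  write_family_gff3(sim$loci, file.path(dir, "loci.gff3"))
  write_segment_map(sim$segment_map, file.path(dir, "segment_map.tsv"))
  truth <- sim$truth
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
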