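#' Pipeline configuration
#'
#' Builds the nested configuration for [run_all()]: global seed, output
#' directory, and one section per stage mirroring the stage parameters
#' ([alignment_params()], [orthology_thresholds()], [phylo_params()], the
#' conserved-window rule, expression thresholds and [simulation_config()]).
#' `x` may be a YAML file path or a nested list; supplied values override
#' the defaults and unknown keys are rejected.
#'
#' @param x `NULL`, a YAML file path, or a nested list of overrides.
#' @return A validated nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = NULL) {
  defaults <- list(
    seed = 1L,
    out_dir = "grasfam_out",
    stages = c("structure", "phylogeny", "motifs", "orthology",
               "duplication", "expression"),
    alignment = list(gap_open = 11, gap_extend = 1,
                     lambda = 0.267, kappa = 0.041),
    orthology = list(max_evalue = 1e-20, min_identity = 0.40),
    phylogeny = list(min_site_coverage = 0.95, bootstrap_replicates = 100L,
                     collapse_below = 0.30, distance_model = "jtt_corrected"),
    motifs = list(min_score = 0.7, min_identity = 0.50, min_length = 10L),
    duplication = list(max_gap_bp = 250000, tolerance_bp = 0),
    expression = list(po_log2_threshold = 8, inclusive = TRUE,
                      coexpr_distance_cutoff = 0.2),
    simulation = list(n_subfamilies = 13L, members_per_subfamily = 4L,
                      protein_length = c(400L, 700L),
                      within_subfamily_divergence = 0.1,
                      between_subfamily_divergence = 0.8,
                      ortholog_divergence = 0.1,
                      n_tandem_arrays = 2L, n_segmental_pairs = 3L,
                      lost_subfamily_fraction = 0.25,
                      n_lineage_duplicates = 0L,
                      expr_n_conditions = 50L, module_size = 10L,
                      module_pcc = 0.9, n_tissue_specific = 6L)
  )
  user <- if (is.null(x)) list()
          else if (is.character(x)) yaml::read_yaml(x)
          else x
  cfg <- merge_config(defaults, user, path = "config")
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("unknown ", path, " key(s): ", paste(unknown, collapse = ", ")))
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], as.list(user[[key]]),
                                      paste0(path, "$", key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

config_alignment_params <- function(config) {
  alignment_params(gap_open = config$alignment$gap_open,
                   gap_extend = config$alignment$gap_extend,
                   lambda = config$alignment$lambda,
                   kappa = config$alignment$kappa)
}

#' Run the characterization pipeline end to end
#'
#' Executes the requested stages in the family-characterization order
#' (structure, phylogeny and subfamily assignment, motifs, orthology,
#' duplication, expression), writes per-stage tab-separated outputs plus a
#' JSON summary report (package version, seed, config hash, per-stage
#' counts) into `config$out_dir`, and returns all results. With
#' `inputs = NULL` the synthetic generator supplies a fully labeled dataset
#' from `config$simulation`, and the summary additionally reports
#' recovery against the ground truth. A stage failure aborts with a
#' stage-named error; outputs of earlier stages are retained on disk.
#'
#' @param config A [pipeline_config()] object (or anything
#'   [pipeline_config()] accepts).
#' @param inputs `NULL`, or a list with any of `loci`, `genome1`, `genome2`,
#'   `segment_map`, `expr`, `design`, `anchors`, `subfamilies`.
#' @param stages Stages to run; defaults to `config$stages`.
#' @return A list of per-stage results (invisible), including `report`.
#' @export
run_all <- function(config = pipeline_config(), inputs = NULL, stages = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(stages)) stages <- config$stages
  unknown <- setdiff(stages, c("structure", "phylogeny", "motifs", "orthology",
                               "duplication", "expression"))
  if (length(unknown) > 0L) {
    abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage ", name, " failed: ", conditionMessage(e)))
    })
  }
  results <- list()
  truth <- NULL

  if (is.null(inputs)) {
    sim_cfg <- do.call(simulation_config,
                       c(list(seed = config$seed), config$simulation))
    sim <- simulate_family(sim_cfg)
    se <- simulate_expression(sim_cfg, sim$genome1$id)
    truth <- c(sim$truth, se$truth)
    anchors <- sim$truth$subfamilies |>
      dplyr::filter(.data$genome == "GV") |>
      dplyr::group_by(.data$subfamily) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::select("id", "subfamily")
    inputs <- list(loci = sim$loci, genome1 = sim$genome1,
                   genome2 = sim$genome2, segment_map = sim$segment_map,
                   expr = se$expr, design = se$design, anchors = anchors)
    results$simulation <- sim
  }
  aln_params <- config_alignment_params(config)

  if ("structure" %in% stages) {
    results$structure <- run_stage("structure", {
      if (is.null(inputs$loci)) abort("no locus table supplied")
      s <- summarize_structure(inputs$loci)
      readr::write_tsv(tidy(s), file.path(config$out_dir, "structure_lengths.tsv"))
      readr::write_tsv(glance(s), file.path(config$out_dir, "structure_summary.tsv"))
      s
    })
  }

  if ("phylogeny" %in% stages) {
    results$phylogeny <- run_stage("phylogeny", {
      if (is.null(inputs$genome1)) abort("no protein set supplied")
      msa <- progressive_msa(inputs$genome1, aln_params)
      masked <- mask_columns(msa, config$phylogeny$min_site_coverage)
      pp <- phylo_params(
        min_site_coverage = config$phylogeny$min_site_coverage,
        bootstrap_replicates = config$phylogeny$bootstrap_replicates,
        collapse_below = config$phylogeny$collapse_below,
        distance_model = config$phylogeny$distance_model,
        seed = config$seed)
      tree <- bootstrap_consensus(masked, pp)
      ape::write.tree(tree, file.path(config$out_dir, "consensus_tree.nwk"))
      assignment <- NULL
      if (!is.null(inputs$anchors)) {
        assignment <- assign_subfamilies(tree, inputs$anchors)
        readr::write_tsv(assignment, file.path(config$out_dir, "subfamilies.tsv"))
      }
      list(msa = msa, masked = masked, tree = tree, assignment = assignment)
    })
  }

  subfamilies <- inputs$subfamilies
  if (is.null(subfamilies) && !is.null(results$phylogeny$assignment)) {
    subfamilies <- results$phylogeny$assignment |>
      dplyr::filter(!is.na(.data$subfamily)) |>
      dplyr::select("id", "subfamily")
  }
  if (is.null(subfamilies) && !is.null(inputs$loci)) {
    # fall back on member symbols, which encode the subfamily by convention
    subfamilies <- inputs$loci |>
      dplyr::distinct(.data$locus_id, .data$short_name) |>
      dplyr::transmute(id = .data$locus_id,
                       subfamily = subfamily_from_symbol(.data$short_name))
  }

  if ("motifs" %in% stages) {
    results$motifs <- run_stage("motifs", {
      if (is.null(inputs$genome1)) abort("no protein set supplied")
      catalog <- read_motif_catalog()
      anns <- purrr::map(seq_len(nrow(inputs$genome1)), function(i) {
        annotate_motifs(inputs$genome1[i, ], catalog,
                        min_score = config$motifs$min_score)
      })
      hits <- purrr::map_dfr(anns, tidy)
      readr::write_tsv(hits, file.path(config$out_dir, "motif_hits.tsv"))
      write_motif_gff3(anns, file.path(config$out_dir, "motif_hits.gff3"))
      anns
    })
  }

  if ("orthology" %in% stages) {
    results$orthology <- run_stage("orthology", {
      if (is.null(inputs$genome1) || is.null(inputs$genome2)) {
        abort("orthology needs two genomes")
      }
      thr <- orthology_thresholds(config$orthology$max_evalue,
                                  config$orthology$min_identity)
      calls <- classify_orthologs(inputs$genome1, inputs$genome2, thr, aln_params)
      readr::write_tsv(calls, file.path(config$out_dir, "orthology_calls.tsv"))
      calls
    })
  }

  if ("duplication" %in% stages) {
    results$duplication <- run_stage("duplication", {
      if (is.null(inputs$loci)) abort("no locus table supplied")
      if (is.null(subfamilies)) abort("no subfamily labels available")
      tand <- tandem_arrays(inputs$loci, subfamilies,
                            max_gap_bp = config$duplication$max_gap_bp)
      readr::write_tsv(tand, file.path(config$out_dir, "tandem_arrays.tsv"))
      seg <- NULL
      if (!is.null(inputs$segment_map)) {
        seg <- segmental_pairs(inputs$loci, subfamilies, inputs$segment_map,
                               tolerance_bp = config$duplication$tolerance_bp)
        readr::write_tsv(seg, file.path(config$out_dir, "segmental_pairs.tsv"))
      }
      list(tandem = tand, segmental = seg)
    })
  }

  if ("expression" %in% stages) {
    results$expression <- run_stage("expression", {
      if (is.null(inputs$expr) || is.null(inputs$design)) {
        abort("expression needs a matrix and a replicate design")
      }
      avg <- average_replicates(inputs$expr, inputs$design)
      po <- po_attribution(avg, threshold = config$expression$po_log2_threshold,
                           inclusive = config$expression$inclusive)
      clusters <- coexpression_clusters(avg,
                                        cutoff = config$expression$coexpr_distance_cutoff)
      readr::write_tsv(avg, file.path(config$out_dir, "expression_averaged.tsv"))
      readr::write_tsv(po, file.path(config$out_dir, "po_attribution.tsv"))
      readr::write_tsv(clusters, file.path(config$out_dir, "coexpression_clusters.tsv"))
      list(averaged = avg, po = po, clusters = clusters)
    })
  }

  report <- list(
    package_version = as.character(utils::packageVersion("grasfam")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages_run = stages,
    counts = list(
      n_loci = if (!is.null(results$structure)) results$structure$n_loci else NULL,
      n_motif_hits = if (!is.null(results$motifs))
        sum(vapply(results$motifs, function(a) nrow(a$hits), integer(1))) else NULL,
      n_one_to_one = if (!is.null(results$orthology))
        sum(results$orthology$category == "one_to_one") else NULL,
      n_tandem_arrays = if (!is.null(results$duplication))
        dplyr::n_distinct(results$duplication$tandem$array) else NULL,
      n_segmental_pairs = if (!is.null(results$duplication) &&
                              !is.null(results$duplication$segmental))
        nrow(results$duplication$segmental) else NULL,
      n_coexpression_clusters = if (!is.null(results$expression))
        dplyr::n_distinct(stats::na.omit(results$expression$clusters$cluster)) else NULL
    )
  )
  if (!is.null(truth)) results$truth <- truth
  results$report <- report
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
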