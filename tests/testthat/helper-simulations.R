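# Simulations reused across test files. The full-scale family (13 subfamilies
# x 4 members, 400-700 aa) is expensive to build and align, so it is cached
# for the session; the small family keeps unit tests fast.

.sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    .sim_cache$default <- simulate_family(simulation_config(seed = 1L))
  }
  .sim_cache$default
}

default_sim_msa_masked <- function() {
  if (is.null(.sim_cache$default_masked)) {
    sim <- default_sim()
    msa <- progressive_msa(sim$genome1)
    .sim_cache$default_masked <- mask_columns(msa, 0.95)
  }
  .sim_cache$default_masked
}

small_config <- function(seed = 101L, expr_n_conditions = 50L, ...) {
  simulation_config(seed = seed, n_subfamilies = 4L, members_per_subfamily = 3L,
                    protein_length = c(320L, 380L), n_tandem_arrays = 1L,
                    n_segmental_pairs = 1L, lost_subfamily_fraction = 0.25,
                    module_size = 4L, expr_n_conditions = expr_n_conditions,
                    n_tissue_specific = 2L, ...)
}

small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    .sim_cache$small <- simulate_family(small_config())
  }
  .sim_cache$small
}

truth_anchors <- function(sim) {
  sim$truth$subfamilies |>
    dplyr::filter(genome == "GV") |>
    dplyr::group_by(subfamily) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(id, subfamily)
}

gv_subfamilies <- function(sim) {
  sim$truth$subfamilies |>
    dplyr::filter(genome == "GV") |>
    dplyr::select(id, subfamily)
}
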