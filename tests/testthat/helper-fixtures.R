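# Shared fixtures, memoized so expensive simulations and pham
# assignments run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# The six-phage reclustering scenario (plus HGT carrier phages).
scenario_population <- function(seed = 1) {
  memo(paste0("scenario_", seed),
       simulate_population(bluefeather_scenario_params(seed = seed)))
}

scenario_assignment <- function(seed = 1) {
  memo(paste0("scenario_assign_", seed),
       assign_phams(population_proteins(scenario_population(seed)$genomes)))
}

# A small, fast generic population for io/pipeline plumbing tests.
small_params <- function(seed = 7, ...) {
  defaults <- list(seed = seed, n_clusters = 2L,
                   phages_per_cluster = c(2L, 2L),
                   genes_per_genome = c(8L, 10L),
                   pham_universe_size = 60L,
                   protein_len = c(60L, 120L),
                   orphams_per_genome = 1L)
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

small_population <- function() {
  memo("small_pop", simulate_population(small_params()))
}

six_metadata <- function() {
  data.frame(
    phage_name = c("BlueFeather", "Corgi", "Idaho", "Noely", "Whytu", "Yavru"),
    host = c(rep("Arthrobacter globiformis B-2979", 4),
             rep("Arthrobacter sp. ATCC 21022", 2)),
    original_cluster = c("singleton", "FE", "FE", "FE", "FI", "FI"),
    stringsAsFactors = FALSE)
}
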