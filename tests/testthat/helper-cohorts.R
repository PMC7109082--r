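# Shared simulated cohorts, generated once per test run. The small
# genome keeps unit tests fast; acceptance tests build their own
# cohorts at the study sizes.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

small_genome_spec <- list(n_genes = 80L, n_chromosomes = 2L,
                          cds_mean_bp = 900, cds_sdlog = 0.4,
                          driver_fraction = 0.25)

small_panel_sizes <- c(PanelA = 20L, PanelB = 30L, PanelC = 38L)

small_config <- function(seed = 7L, n = 40L, enrichment = 2, ...) {
  sim_config(seed = seed, n_samples = n, driver_enrichment = enrichment,
             genome_spec = small_genome_spec,
             panel_sizes = small_panel_sizes, ...)
}

small_cohort <- function() {
  cached("small", simulate_cohort(small_config()))
}

small_profiles <- function() {
  cached("small_profiles", cohort_profiles(small_cohort()))
}

# default-scale cohort shared by generator property tests
default_cohort <- function() {
  cached("default", simulate_cohort(sim_config(seed = 7L, n_samples = 150L)))
}
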