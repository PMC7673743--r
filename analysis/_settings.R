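# Shared settings for the analysis drivers.  Every stage derives its
# randomness from this one seed, so each numbered script can be run on its
# own and still reproduce the same study.

library(tadaregulon)

SEED <- 1L
RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

study_config <- function(seed = SEED) pipeline_config(sim_config(seed = seed))

# deterministic regeneration of the synthetic study for any stage
study_inputs <- function(seed = SEED) {
  cfg <- study_config(seed)
  sim <- simulate_genome(cfg$sim)
  list(cfg = cfg, genome = sim$genome, truth = sim$truth,
       fragmap = build_gatc_fragment_map(sim$genome))
}
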