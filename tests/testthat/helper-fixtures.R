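# Shared fixtures, built once per test run. The default-sized simulation
# is reused across module tests; a reduced configuration is available for
# tests that need an independent, faster genome.

.fixtures <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- sim_config(seed = 101)
    .fixtures$cfg <- cfg
    .fixtures$sim <- simulate_genome(cfg)
    .fixtures$cnt <- simulate_counts(.fixtures$sim, cfg)
  }
  list(cfg = .fixtures$cfg, sim = .fixtures$sim, cnt = .fixtures$cnt)
}

small_config <- function(seed = 7, ...) {
  args <- list(seed = seed, n_chromosomes_per_subgenome = 1L,
               chromosome_length = 250000L, n_genes = 40L, n_lnc_u = 20L,
               n_lnc_i = 5L, n_lnc_x = 5L, n_homolog_pairs = 2L,
               n_shuffled_pairs = 1L, n_decoys_per_rule = 3L,
               n_mrna_copies = 10L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# a deterministic amplicon with one guide+PAM site
fixture_amplicon <- function(seed = 5, flank5 = 100, flank3 = 120) {
  set.seed(seed)
  guide <- "GACTGACTGACTGACTGACT"
  repeat {
    amp <- paste0(random_seq(flank5), guide, "TGG", random_seq(flank3))
    ok <- tryCatch({
      locate_guide(amp, guide)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(list(amplicon = amp, guide = guide))
  }
}
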