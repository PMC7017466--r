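# The 50-ear benchmark population is expensive; generate it once and share
# it across the acceptance checks that score different aspects of the same
# run (count accuracy, weight fidelity, count fidelity).

.population_cache <- new.env(parent = emptyenv())

population_experiment <- function() {
  if (is.null(.population_cache$ex)) {
    .population_cache$ex <- grain_recovery_experiment(n_ears = 50L,
                                                      rng_seed = 1L)
  }
  .population_cache$ex
}
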