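# Shared desk-scale fixtures, all generated in code.

# A small but non-trivial simulated dataset (S = 5, n = 40).
tiny_truth <- function(seed = 3, ...) {
  simulate_dataset(simulation_config(n = 40, S = 5, p = 1, a = c(0.8, 0.5),
                                     seed = seed, ...))
}

# Fast sampler profile for smoke-level fits in unit tests.
quick_sc <- function(seed = 5, chains = 2, iterations = 600) {
  sampler_config(chains = chains, iterations = iterations, seed = seed,
                 max_leapfrog = 64)
}

# Random count matrix for property tests.
random_counts <- function(n, S, lambda = 30) {
  count_table(matrix(rpois(n * S, lambda), n, S))
}
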