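# shared small-scale simulation helper for unit tests
small_sim <- function(seed = 42, chrom_length = 1e7, ff = 0.13, ...) {
  simulate_family(sim_config(chrom_length = chrom_length, ff = ff,
                             seed = seed, ...))
}

# random single-locus inputs for property-style suites
random_locus_cases <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    mat_gt = sample(0:2, n, replace = TRUE),
    pat_gt = sample(0:2, n, replace = TRUE),
    C = sample(c(0.05, 0.1, 0.2), n, replace = TRUE),
    depth = sample(c(50L, 100L, 200L), n, replace = TRUE),
    alt_frac = runif(n)
  ) |>
    dplyr::mutate(alt_count = rbinom(n, .data$depth, .data$alt_frac),
                  ref_count = .data$depth - .data$alt_count)
}
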