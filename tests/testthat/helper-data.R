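# Shared synthetic study conditions: two clearly disjoint-parameter species.
# A: 3 short flashes (0.10 s) with 0.30 s gaps; B: 4 long flashes (0.20 s)
# with 0.80 s gaps. Parameters are on the scale of real field populations.
species_a <- function() species_params("A", 3, 0.4, 0.30, 0.02, 0.10, 0.01)
species_b <- function() species_params("B", 4, 0.5, 0.80, 0.05, 0.20, 0.02)

two_species_dataset <- function(n_per_species, seed) {
  dplyr::bind_rows(
    generate_population(species_a(), n_per_species, seed = seed),
    generate_population(species_b(), n_per_species, seed = seed + 1000L)
  )
}

# Small fast GRU config for synthetic experiments (defaults in gru_config()
# are the full-scale protocol; tests use a CPU-scale instance).
test_gru_config <- function(n_species = 2, seed = 99L) {
  gru_config(
    n_species = n_species, n_layers = 2, hidden_dim = 32,
    learning_rate = 0.01, grad_clip_norm = 1,
    early_stop_patience = 8, max_epochs = 40, seed = seed
  )
}

random_bits <- function(len, p = 0.5) {
  v <- as.integer(runif(len) < p)
  v[1] <- 1L
  v[len] <- 1L
  paste(v, collapse = "")
}
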