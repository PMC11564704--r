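# Memoized expensive pipeline runs shared across acceptance blocks.
# Study-shaped but size-reduced conditions: 59 channels, 48 epochs
# (36 healthy / 12 AD, ~the study's imbalance), 3-s epochs at 250 Hz.
.run_cache <- new.env(parent = emptyenv())

acceptance_conditions <- function(profiles = NULL, seed = 1L) {
  if (is.null(profiles)) profiles <- default_profiles_for_tests()
  synth_config(n_channels = 59L, n_epochs = c(healthy = 36L, AD = 12L),
               epoch_length = 750L, sampling_rate = 250,
               profiles = profiles, seed = seed)
}

default_profiles_for_tests <- function() {
  list(healthy = c(delta = 1.0, theta = 0.5, alpha = 2.0, beta = 0.8),
       AD      = c(delta = 1.2, theta = 2.0, alpha = 0.5, beta = 0.6))
}

null_profiles_for_tests <- function() {
  p <- default_profiles_for_tests()
  list(healthy = p$healthy, AD = p$healthy)
}

cached_run <- function(key, profiles, seed) {
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  collection <- generate_synthetic(acceptance_conditions(profiles, seed))
  run <- lattice_run(collection, seed = seed)
  .run_cache[[key]] <- run
  run
}

separated_run <- function(seed) {
  cached_run(paste0("sep", seed), default_profiles_for_tests(), seed)
}

null_run <- function(seed) {
  cached_run(paste0("null", seed), null_profiles_for_tests(), seed)
}
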