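# Shared fixtures, generated in code. The "easy" regime (separability 0.2)
# gives well-separated classes so model sanity checks are cheap and stable.

easy_data <- function(n_per_class = 60, seed = 42, separability = 0.2) {
  generate_postures(n_per_class, seed = seed, separability = separability)
}

easy_split <- function(n_per_class = 60, seed = 42, separability = 0.2) {
  d <- easy_data(n_per_class, seed, separability)
  split_dataset(extract_features(d), seed = seed)
}

# A fast DNDT spec for unit tests (fewer epochs than the tuned default).
fast_dndt_spec <- function(seed = 0, epochs = 60L) {
  estimator_spec("dndt", list(epochs = epochs), seed = seed)
}
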