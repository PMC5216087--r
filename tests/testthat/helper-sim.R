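# Small simulation fixtures shared across test files. Explicit breed sizes
# bypass the 7-12 recruitment range so tests stay fast.
small_config <- function(seed = 1, effect_log2fc = 3, ...) {
  defaults <- list(
    breeds = c(A = 8, B = 8, C = 8, D = 8), n_features = 150,
    n_cluster_bases = 10, max_satellites = 2,
    group1_breeds = "A", metaclass2_breeds = c("A", "C"), mixed_breed = "D",
    n_diet_bases = 8, n_metaclass2_bases = 6,
    n_diet_pathways = 2, n_metaclass2_pathways = 2,
    unique_spec = c(B = 3), effect_log2fc = effect_log2fc, seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

fast_scheme <- function(seed = 1, n_bootstraps = 10, ntree = 100, ...) {
  bootstrap_scheme(n_bootstraps = n_bootstraps, ntree = ntree, seed = seed,
                   ...)
}

# matrix with pure noise features and no class structure
noise_matrix <- function(n = 24, p = 60, seed = 1) {
  set.seed(seed)
  m <- matrix(2^rnorm(n * p, 14, 1), n, p)
  feature_matrix(m, mz = seq(200.1234, by = 1.0101, length.out = p),
                 rt = rep(120, p))
}
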