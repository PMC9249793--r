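# Shared fixtures: small study configurations that keep the suite fast
# while preserving the panel design (31 materials, 3 classes).

tiny_config <- function(seed = 1, effect_size = 2,
                        features_per_layer = c(mrna = 60, proteomics = 30, physchem = 12),
                        ...) {
  sim_config(
    seed = seed, effect_size = effect_size,
    features_per_layer = features_per_layer, ...
  )
}

# Matrix view of one layer of a study.
layer_mat <- function(study, layer) {
  m <- as.matrix(study$panel[[layer]][, -1])
  rownames(m) <- study$panel[[layer]]$material
  m
}

# Class factor named by material for a labeling tibble.
label_vec <- function(labeling) {
  setNames(factor(labeling$class), labeling$material)
}

# Three well-separated spherical point clouds in d dimensions.
separated_clouds <- function(n_per = 10, d = 4, gap = 8, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * d), n_per, d),
    matrix(rnorm(n_per * d, mean = gap), n_per, d),
    matrix(rnorm(n_per * d, mean = 2 * gap), n_per, d)
  )
  rownames(x) <- sprintf("M%02d", seq_len(nrow(x)))
  x
}

# GA settings small enough for exhaustive-oracle comparisons.
small_ga <- function(max_subset_size = 2) {
  ga_config(
    population_size = 24, n_generations = 15, fitness_folds = 3,
    ntree = 60, max_subset_size = max_subset_size
  )
}
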