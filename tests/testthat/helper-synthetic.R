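# small fixtures shared across test files; everything is generated in code

tiny_grid <- function(shape = c(12, 14, 10)) volume_grid(shape)

tiny_design <- function(trials_per_run = 10, n_runs = 2, seed = 1, ...)
  build_design("exp1", n_runs = n_runs, trials_per_run = trials_per_run,
               seed = seed, ...)

# a trial_pattern_set over a flat p-voxel strip, values supplied directly
flat_patterns <- function(values, condition, run, ratings = NULL) {
  p <- ncol(values)
  grid <- volume_grid(c(p, 1, 1))
  mask <- array(TRUE, grid$shape)
  trial_pattern_set(values, condition, run, grid, mask, ratings = ratings)
}

# pure-noise pattern set: k conditions x n trials each, p voxels
noise_patterns <- function(n_per_class = 10, p = 30, k = 4, n_runs = 2,
                           conditions = c("sour", "sweet", "bitter", "salty"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- rep(conditions[seq_len(k)], each = n_per_class)
  n <- length(conds)
  run <- rep(rep(seq_len(n_runs), length.out = n_per_class), k)
  flat_patterns(matrix(rnorm(n * p), n, p), conds, run)
}
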