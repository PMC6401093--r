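# shared settings for the analysis drivers: one synthetic cohort at a
# desk-scale grid (2 mm voxels), regenerated deterministically by seed
library(gustotope)

settings <- list(
  grid_shape = c(20L, 24L, 18L),
  n_subjects = 12L,
  seed = 20240101L,
  n_perm_group = 2000L,
  n_perm_loso = 500L,
  n_null_threshold = 2000L,
  n_draws_cells = 10000L
)

cohort_grid <- function() volume_grid(settings$grid_shape)

cohort_model <- function(...) ground_truth_model(cohort_grid(), ...)

cohort_design <- function(s) build_design("exp1", seed = settings$seed + 500L + s)

# one subject's trial patterns under `model` (demeaned for multivoxel
# analyses; raw for the univariate voxel-tuning analyses)
cohort_subject <- function(s, model, demean = TRUE) {
  su <- generate_subject(cohort_design(s), model, mode = "patterns",
                         seed = settings$seed + s)
  p <- if (demean) demean_patterns(su$patterns) else su$patterns
  p$ratings <- su$ratings
  p
}

results_dir <- "results"
scratch_dir <- "scratch/analysis"
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(scratch_dir, showWarnings = FALSE, recursive = TRUE)
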