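#' Searchlight taste discriminability maps
#'
#' Slides a sphere across every mask voxel, extracts the in-sphere
#' trial patterns and computes the leave-one-stimulus-pair-out LDA
#' accuracy for every pair of conditions.  Each taste's discriminability
#' at a voxel is its accuracy averaged over the comparisons with every
#' other condition (tasteless included by default, e.g. sour vs sweet,
#' sour vs bitter, sour vs salty, sour vs tasteless).  Spheres exiting
#' the mask keep their available in-mask voxels as long as at least
#' `min_frac` of the sphere remains, otherwise the voxel is `NA`.
#'
#' @param patterns a [trial_pattern_set()].
#' @param spec a [sphere_offsets()] spec; default 4 mm radius on the
#'   grid's voxel size.
#' @param include_tasteless average over comparisons with the tasteless
#'   control as well (default) or over taste-taste pairs only.
#' @param min_frac minimum in-mask fraction of the sphere.
#' @inheritParams pairwise_accuracy
#' @return named list, one `accuracy_map` per taste (fields `acc`: 3D
#'   array in `[0, 1]`, `NA` outside the analysable mask; `taste`;
#'   `chance = 0.5`).
#' @export
discriminability_maps <- function(patterns, spec = NULL,
                                  include_tasteless = TRUE, min_frac = 0.5,
                                  scheme = c("all-pairs", "matched"),
                                  shrinkage = 0) {
  scheme <- match.arg(scheme)
  grid <- patterns$grid
  if (is.null(spec)) spec <- sphere_offsets(4, grid$voxel_size_mm[1])
  n_sphere <- nrow(spec$offsets)
  mask <- patterns$mask
  if (sum(mask) < n_sphere) stop("mask smaller than one searchlight sphere")
  conds <- unique(patterns$condition)
  tastes <- taste_labels(conds)
  avg_over <- if (include_tasteless) conds else tastes
  y <- match(patterns$condition, conds) - 1L
  lam <- shrinkage_lambda(shrinkage)
  matched <- scheme == "matched"

  shp <- grid$shape
  col_of <- array(0L, shp)
  col_of[mask] <- seq_len(sum(mask))
  vox_ijk <- which(mask, arr.ind = TRUE)
  min_vox <- ceiling(min_frac * n_sphere)

  acc <- matrix(NA_real_, sum(mask), length(tastes),
                dimnames = list(NULL, tastes))
  off <- spec$offsets
  for (v in seq_len(nrow(vox_ijk))) {
    pts <- sweep(off, 2, vox_ijk[v, ], `+`)
    ok <- pts[, 1] >= 1 & pts[, 1] <= shp[1] &
          pts[, 2] >= 1 & pts[, 2] <= shp[2] &
          pts[, 3] >= 1 & pts[, 3] <= shp[3]
    cols <- col_of[pts[ok, , drop = FALSE]]
    cols <- cols[cols > 0L]
    if (length(cols) < min_vox) next
    am <- pair_accuracy_matrix_cpp(patterns$values[, cols, drop = FALSE], y,
                                   length(conds), lam, matched)
    dimnames(am) <- list(conds, conds)
    for (ta in tastes)
      acc[v, ta] <- mean(am[ta, setdiff(avg_over, ta)])
  }
  lapply(stats::setNames(tastes, tastes), function(ta) {
    vol <- array(NA_real_, shp)
    vol[mask] <- acc[, ta]
    structure(list(acc = vol, taste = ta, chance = 0.5),
              class = "accuracy_map")
  })
}

#' Single-subject accuracy significance threshold
#'
#' Builds the null distribution of a taste's average pairwise LDA
#' accuracy for one searchlight sphere and returns its upper
#' `1 - alpha` quantile: the per-subject accuracy cut-off corresponding
#' to p < alpha uncorrected.  Two null constructions are available:
#' `"noise"` simulates fresh Gaussian patterns per realisation
#' (exchangeable with label permutation on signal-free data), while
#' `"permutation"` reshuffles the supplied patterns' class labels
#' within run, preserving run balance.
#'
#' With the standard 3 T geometry (20 trials per class, 4 comparisons
#' per taste, 33-voxel sphere) and alpha 0.05 the threshold comes out
#' at about 58.7% accuracy.
#'
#' @param n_per_class trials per condition.
#' @param n_comparisons pairwise comparisons averaged per taste.
#' @param n_features voxels in the sphere.
#' @param alpha nominal uncorrected significance level.
#' @param n_null number of null realisations (warning below 100).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param null `"noise"` or `"permutation"`.
#' @param patterns,run required for the permutation null: a trial x
#'   feature matrix of one sphere's patterns with per-trial labels in
#'   `labels` and run indices in `run`.
#' @param labels per-trial labels for the permutation null; the first
#'   label is the tested taste.
#' @inheritParams pairwise_accuracy
#' @return list with `threshold` (accuracy in `[0, 1]`), `null_values`,
#'   `alpha`, `n_null`.
#' @export
subject_threshold <- function(n_per_class = 20, n_comparisons = 4,
                              n_features = 33, alpha = 0.05, n_null = 2000,
                              seed = NULL, null = c("noise", "permutation"),
                              patterns = NULL, labels = NULL, run = NULL,
                              scheme = c("all-pairs", "matched"),
                              shrinkage = 0) {
  null <- match.arg(null)
  scheme <- match.arg(scheme)
  stopifnot(alpha > 0, alpha < 1)
  if (n_null < 100) warning("n_null < 100: the null quantile will be unstable")
  use_seed(seed)
  lam <- shrinkage_lambda(shrinkage)
  matched <- scheme == "matched"
  vals <- numeric(n_null)
  if (null == "noise") {
    for (i in seq_len(n_null)) {
      Xt <- matrix(rnorm(n_per_class * n_features), n_per_class)
      vals[i] <- mean(vapply(seq_len(n_comparisons), function(j) {
        lda_pair_cv_cpp(Xt, matrix(rnorm(n_per_class * n_features), n_per_class),
                        lam, matched)
      }, numeric(1)))
    }
  } else {
    stopifnot(!is.null(patterns), !is.null(labels), !is.null(run))
    patterns <- as.matrix(patterns)
    classes <- unique(labels)
    target <- classes[1]
    others <- setdiff(classes, target)
    for (i in seq_len(n_null)) {
      perm <- labels
      for (r in unique(run)) {
        sel <- run == r
        perm[sel] <- sample(labels[sel])
      }
      vals[i] <- mean(vapply(others, function(ob) {
        lda_pair_cv_cpp(patterns[perm == target, , drop = FALSE],
                        patterns[perm == ob, , drop = FALSE], lam, matched)
      }, numeric(1)))
    }
  }
  list(threshold = unname(quantile(vals, 1 - alpha, type = 7)),
       null_values = vals, alpha = alpha, n_null = n_null)
}
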