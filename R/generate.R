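#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with a response peak at 6 s, an
#' undershoot peaking at 16 s and a peak-to-undershoot ratio of 6,
#' normalised to unit peak so that regression coefficients carry the
#' event amplitude.
#'
#' @param t time in seconds (vector).
#' @param peak_delay,undershoot_delay gamma peak times in s.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return numeric vector of HRF values.
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h[t < 0] <- 0
  pk <- stats::dgamma(peak_delay - 1, shape = peak_delay, rate = 1)
  h / pk
}

#' Per-trial HRF regressors for one run
#'
#' Convolves each trial's boxcar (onset, duration) with the canonical
#' HRF on an oversampled time grid and samples at volume acquisition
#' times.
#'
#' @param onsets,durations trial timing in s (within-run).
#' @param n_vols number of volumes in the run.
#' @param tr_s repetition time in s.
#' @param oversample temporal oversampling factor.
#' @return matrix of `n_vols` rows, one column per trial.
#' @export
hrf_regressors <- function(onsets, durations, n_vols, tr_s, oversample = 16) {
  dt <- tr_s / oversample
  n_fine <- n_vols * oversample
  hrf_len <- ceiling(32 / dt)
  h <- canonical_hrf(seq(0, by = dt, length.out = hrf_len))
  out <- matrix(0, n_vols, length(onsets))
  vol_idx <- 1 + round((seq_len(n_vols) - 1) * tr_s / dt)
  for (i in seq_along(onsets)) {
    box <- numeric(n_fine + hrf_len)
    i0 <- 1 + round(onsets[i] / dt)
    i1 <- min(n_fine, 1 + round((onsets[i] + durations[i]) / dt))
    if (i0 > n_fine) stop("trial onset beyond run duration")
    box[i0:max(i0, i1)] <- 1
    conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_fine)]
    out[, i] <- conv[vol_idx]
  }
  out
}

# smoothed unit-variance Gaussian noise restricted to mask voxels;
# one column of length sum(mask) per draw.  All draws are smoothed in
# one batched band-matrix pass per axis.
smooth_unit_noise <- function(grid, mask, fwhm_mm, n_draws) {
  shp <- grid$shape
  fac <- smooth_noise_sd_factor(fwhm_mm, grid$voxel_size_mm)
  w <- matrix(rnorm(prod(shp) * n_draws), prod(shp), n_draws)
  w <- batch_smooth(w, shp, fwhm_mm, grid$voxel_size_mm)
  w[as.vector(mask), , drop = FALSE] / fac
}

#' Trial-pattern container
#'
#' Holds a trial x voxel matrix of activation estimates (t-values after
#' GLM extraction) on the masked grid, with per-trial condition labels,
#' run indices and optional hedonic ratings.
#'
#' @param values numeric matrix, trials x mask voxels.
#' @param condition per-trial condition labels.
#' @param run per-trial run indices.
#' @param grid a [volume_grid()].
#' @param mask logical array with `sum(mask) == ncol(values)`.
#' @param ratings optional ratings data.frame as [sample_ratings()].
#' @param demeaned logical flag recording whether per-voxel demeaning
#'   across trials has been applied.
#' @return object of class `trial_pattern_set`.
#' @export
trial_pattern_set <- function(values, condition, run, grid, mask,
                              ratings = NULL, demeaned = FALSE) {
  stopifnot(nrow(values) == length(condition), length(condition) == length(run),
            ncol(values) == sum(mask))
  structure(list(values = values, condition = as.character(condition),
                 run = as.integer(run), grid = grid, mask = mask,
                 ratings = ratings, demeaned = isTRUE(demeaned)),
            class = "trial_pattern_set")
}

#' @export
print.trial_pattern_set <- function(x, ...) {
  cat("<trial_pattern_set> ", nrow(x$values), " trials x ", ncol(x$values),
      " voxels (", if (x$demeaned) "demeaned" else "raw", ")\n", sep = "")
  invisible(x)
}

#' Demean trial patterns per voxel
#'
#' Subtracts each voxel's mean across all trials (taste and tasteless
#' alike), the normalisation applied to trial t-values before multivoxel
#' analysis.
#'
#' @param patterns a [trial_pattern_set()].
#' @return the pattern set with per-voxel zero mean.
#' @export
demean_patterns <- function(patterns) {
  patterns$values <- sweep(patterns$values, 2, colMeans(patterns$values))
  patterns$demeaned <- TRUE
  patterns
}

#' Generate a synthetic subject dataset
#'
#' Draws hedonic ratings, then builds each trial's spatial amplitude map
#' as the sum of its condition's planted taste map and the valence map
#' scaled by the trial's valence score (positivity - negativity).  In
#' `"patterns"` mode those amplitudes plus smooth Gaussian noise are
#' emitted directly as a trial x voxel pattern set (the fast path for
#' validation).  In `"bold"` mode the amplitudes are convolved with the
#' canonical double-gamma HRF to produce run-wise BOLD time series with
#' baseline, per-voxel linear drift and spatially smooth noise, to be
#' fed through [fit_trialwise()].
#'
#' @param design an event design from [build_design()].
#' @param model a [ground_truth_model()].
#' @param mode `"patterns"` or `"bold"`.
#' @param seed integer seed making the subject fully reproducible.
#' @param baseline,drift_sd bold-mode signal offset and per-run drift
#'   slope sd (ignored in patterns mode).
#' @return object of class `subject_dataset` with fields `design`,
#'   `ratings`, `ground_truth`, `grid`, `mask`, `mode`, `seed` and
#'   exactly one of `patterns` (a [trial_pattern_set()]) or `bold`
#'   (volumes x mask-voxel matrix with attribute `tr_s`).
#' @export
generate_subject <- function(design, model, mode = c("patterns", "bold"),
                             seed = NULL, baseline = 100, drift_sd = 0.5) {
  mode <- match.arg(mode)
  if (!any(model$mask)) stop("mask is empty")
  use_seed(seed)
  ratings <- sample_ratings(design, model, seed = NULL)
  v <- valence_score(ratings$positivity, ratings$negativity)
  n <- nrow(design)
  # trial x voxel amplitude: planted taste map + valence signal
  amp <- t(model$taste_patterns[, design$condition, drop = FALSE]) +
    valence_component(model, v)

  out <- list(design = design, ratings = ratings, ground_truth = model,
              grid = model$grid, mask = model$mask, mode = mode, seed = seed)
  if (mode == "patterns") {
    if (model$noise_sd > 0)
      amp <- amp + model$noise_sd *
        t(smooth_unit_noise(model$grid, model$mask, model$noise_fwhm_mm, n))
    out$patterns <- trial_pattern_set(amp, design$condition, design$run,
                                      model$grid, model$mask, ratings = ratings)
  } else {
    tr <- attr(design, "tr_s")
    nv <- attr(design, "n_vols_per_run")
    runs <- sort(unique(design$run))
    nvox <- sum(model$mask)
    bold <- matrix(0, nv * length(runs), nvox)
    for (r in runs) {
      sel <- design$run == r
      R <- hrf_regressors(design$onset[sel], design$duration[sel], nv, tr)
      seg <- R %*% amp[sel, , drop = FALSE]
      drift <- outer(seq_len(nv) / nv, rnorm(nvox, sd = drift_sd))
      noise <- if (model$noise_sd > 0)
        model$noise_sd * t(smooth_unit_noise(model$grid, model$mask,
                                             model$noise_fwhm_mm, nv))
        else 0
      bold[(which(runs == r) - 1) * nv + seq_len(nv), ] <-
        seg + baseline + drift + noise
    }
    attr(bold, "tr_s") <- tr
    out$bold <- bold
  }
  structure(out, class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("<subject_dataset> mode=", x$mode, ", ", nrow(x$design), " trials, ",
      sum(x$mask), " mask voxels\n", sep = "")
  invisible(x)
}
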