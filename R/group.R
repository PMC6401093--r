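#' Sign-flip max-statistic one-sample permutation test
#'
#' Group inference on per-subject accuracy maps: each map is smoothed
#' (default 4 mm FWHM, kernel renormalised inside the mask), chance
#' (50%) is subtracted, and the observed one-sample t is computed per
#' voxel.  The null distribution of the maximal t within the mask is
#' built by randomly flipping each subject's sign `n_perm` times
#' (default 10,000); the familywise-error threshold is the `1 - alpha`
#' quantile of that max-t distribution, and corrected p-values follow
#' the `(b + 1) / (m + 1)` convention.  When `2^n_subjects <= n_perm`
#' the full sign assignment set is enumerated instead (with a message)
#' and exact p-values `b / m` are returned.  Zero-variance voxels get
#' `NaN` t and are excluded from the max.
#'
#' @param maps list of per-subject 3D accuracy arrays on a common grid
#'   (one taste), or a subjects x mask-voxel matrix.
#' @param mask logical 3D array.
#' @param fwhm_mm smoothing applied to the chance-centred maps.
#' @param voxel_size_mm voxel size for the smoothing kernel.
#' @param alpha familywise error level.
#' @param n_perm requested number of sign flips.
#' @param seed integer seed; `NULL` continues the RNG stream.
#' @param chance value subtracted before testing (0.5 for accuracy).
#' @return object of class `permutation_result`: `t_obs` (3D, `NA`
#'   outside mask), `max_t_null`, `fwe_threshold`, `p_corr` (3D),
#'   `n_perm`, `exhaustive`, `alpha`, `mask`.
#' @export
signflip_onesample <- function(maps, mask, fwhm_mm = 4, voxel_size_mm = 2,
                               alpha = 0.05, n_perm = 10000, seed = NULL,
                               chance = 0.5) {
  use_seed(seed)
  if (is.matrix(maps)) {
    X <- maps - chance
    stopifnot(ncol(X) == sum(mask))
  } else {
    stopifnot(length(maps) >= 2)
    X <- t(vapply(maps, function(m) {
      stopifnot(all(dim(m) == dim(mask)))
      m <- m - chance
      m[!is.finite(m)] <- 0
      if (fwhm_mm > 0)
        m <- smooth_volume(m, fwhm_mm, voxel_size_mm, mask = mask)
      m[mask]
    }, numeric(sum(mask))))
  }
  n <- nrow(X)
  stopifnot(n >= 2)
  nvox <- ncol(X)
  ss <- colSums(X^2)
  mu <- colMeans(X)
  vr <- pmax((ss - n * mu^2) / (n - 1), 0)
  # all-zero voxels carry no data at all: NaN, excluded from the max;
  # constant non-zero voxels are infinitely consistent (t = +/-Inf)
  degen <- ss == 0
  t_obs <- ifelse(degen, NaN, mu / sqrt(vr / n))

  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    message("2^", n, " <= n_perm: enumerating all sign assignments exactly")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  m_perm <- nrow(signs)
  max_t <- rep(-Inf, m_perm)
  live <- which(!degen)
  chunk <- max(1L, floor(2e7 / max(length(live), 1L)))
  if (length(live)) for (lo in seq(1, m_perm, by = chunk)) {
    hi <- min(m_perm, lo + chunk - 1)
    Fm <- signs[lo:hi, , drop = FALSE]
    M <- (Fm %*% X[, live, drop = FALSE]) / n
    V <- pmax(sweep(-n * M^2, 2, ss[live], `+`) / (n - 1), 0)
    Tm <- M / sqrt(V / n)
    Tm[is.nan(Tm)] <- -Inf
    max_t[lo:hi] <- apply(Tm, 1, max)
  }
  if (exhaustive) {
    p_vec <- vapply(t_obs[live], function(tv) mean(max_t >= tv), numeric(1))
  } else {
    p_vec <- vapply(t_obs[live], function(tv) (1 + sum(max_t >= tv)) / (1 + m_perm),
                    numeric(1))
  }
  p_corr_m <- rep(NA_real_, nvox)
  p_corr_m[live] <- p_vec
  thr <- unname(quantile(max_t, 1 - alpha, type = 1))

  to_vol <- function(v) {
    vol <- array(NA_real_, dim(mask))
    vol[mask] <- v
    vol
  }
  structure(list(t_obs = to_vol(t_obs), max_t_null = max_t,
                 fwe_threshold = thr, p_corr = to_vol(p_corr_m),
                 n_perm = m_perm, exhaustive = exhaustive, alpha = alpha,
                 mask = mask),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$n_perm,
      if (x$exhaustive) " exhaustive" else " random", " sign flips, FWE ",
      x$alpha, " threshold t = ", round(x$fwe_threshold, 3), ", ",
      sum(x$t_obs > x$fwe_threshold, na.rm = TRUE), " voxels above\n", sep = "")
  invisible(x)
}

#' Taste conjunction count map
#'
#' Counts, per voxel, how many tastes' observed t exceeds that taste's
#' own familywise-error threshold.  Valid conjunction inference
#' requires significance in all component tests, so the count-`k`
#' stratum is the multi-taste region; a disjunction is never formed.
#'
#' @param results named list of [signflip_onesample()] results, one per
#'   taste, sharing mask and grid.
#' @return integer 3D array (class `conjunction_map`) with values
#'   `0..k` inside the mask, `NA` outside.
#' @export
conjunction_count <- function(results) {
  stopifnot(length(results) >= 1)
  mask <- results[[1]]$mask
  for (r in results)
    if (!identical(dim(r$mask), dim(mask)) || !identical(r$mask, mask))
      stop("permutation results do not share the same mask/grid")
  cnt <- array(0L, dim(mask))
  for (r in results) {
    sig <- r$t_obs > r$fwe_threshold
    sig[is.na(sig)] <- FALSE
    cnt <- cnt + sig
  }
  cnt[!mask] <- NA_integer_
  structure(cnt, k = length(results), class = c("conjunction_map", "array"))
}

#' Leave-one-subject-out conjunction overlap
#'
#' For every left-out subject, computes the four-taste conjunction map
#' at the familywise-error threshold from the remaining subjects; the
#' fold's ROI is the voxel set significant for all tastes.  The overlap
#' volume gives the percentage of leave-one-out maps in which each
#' voxel was significant, and the per-fold ROIs feed downstream
#' analyses of the left-out subject with an independently defined
#' region.
#'
#' @param map_sets list over subjects; each element is a named list of
#'   per-taste 3D accuracy arrays for that subject.
#' @param mask logical 3D array.
#' @param fwhm_mm,voxel_size_mm,alpha,n_perm as [signflip_onesample()].
#' @param seed integer seed; fold f uses `seed + f`.
#' @return list with `overlap` (3D percentage volume), `rois` (list of
#'   logical arrays, one per left-out subject) and `n_folds`.
#' @export
loso_overlap <- function(map_sets, mask, fwhm_mm = 4, voxel_size_mm = 2,
                         alpha = 0.05, n_perm = 1000, seed = NULL) {
  n <- length(map_sets)
  stopifnot(n >= 3)
  tastes <- names(map_sets[[1]])
  rois <- vector("list", n)
  overlap <- array(0, dim(mask))
  for (s in seq_len(n)) {
    rest <- map_sets[-s]
    res <- lapply(stats::setNames(tastes, tastes), function(ta) {
      signflip_onesample(lapply(rest, `[[`, ta), mask, fwhm_mm = fwhm_mm,
                         voxel_size_mm = voxel_size_mm, alpha = alpha,
                         n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + s)
    })
    cnt <- conjunction_count(res)
    roi <- cnt == length(tastes)
    roi[is.na(roi)] <- FALSE
    rois[[s]] <- roi
    overlap <- overlap + roi
  }
  overlap <- 100 * overlap / n
  overlap[!mask] <- NA_real_
  list(overlap = overlap, rois = rois, n_folds = n)
}

#' Dice overlap of two binary regions
#'
#' @param a,b logical arrays of identical shape.
#' @return `2|a & b| / (|a| + |b|)`; `NaN` if both are empty.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a & !is.na(a)
  b <- b & !is.na(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}
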