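#' Odd/even split-half taste correlation matrix
#'
#' Computes each taste's mean voxel activation separately in the odd and
#' even runs (split by run index: runs 1, 3, 5 vs 2, 4) within a region
#' of interest, then correlates the odd-run activation profile of every
#' taste with the even-run profile of every taste across voxels.  Row =
#' taste in odd runs, column = taste in even runs; the matrix need not
#' be symmetric.  A voxel-tuned region yields a dominant diagonal; a
#' shared taste-unspecific response yields uniformly positive entries.
#'
#' @param patterns a [trial_pattern_set()].
#' @param roi region of interest: logical array on the grid, logical or
#'   integer vector over mask voxels, or `NULL` for the whole mask.
#' @param conditions conditions to include; defaults to the tastes
#'   (tasteless excluded, include it explicitly if wanted).
#' @return matrix of class `split_half_matrix` with the Pearson
#'   correlations; constant activation vectors give `NaN` entries with a
#'   warning.
#' @export
split_half_matrix <- function(patterns, roi = NULL, conditions = NULL) {
  cols <- roi_columns(patterns, roi)
  if (!length(cols)) stop("roi is empty")
  if (is.null(conditions)) conditions <- taste_conditions_of(patterns)
  halves <- split_half_means(patterns, cols, conditions)
  if (any(!halves$counts))
    stop("each condition needs at least one trial in both halves")
  k <- length(conditions)
  r <- matrix(NA_real_, k, k, dimnames = list(odd = conditions, even = conditions))
  n_undef <- 0L
  for (a in seq_len(k)) for (b in seq_len(k)) {
    x <- halves$odd[, a]; y <- halves$even[, b]
    if (sd(x) == 0 || sd(y) == 0) {
      n_undef <- n_undef + 1L
      r[a, b] <- NaN
    } else r[a, b] <- cor(x, y)
  }
  if (n_undef > 0)
    warning("constant activation vector(s): ", n_undef,
            " correlation(s) undefined, set to NaN")
  structure(r, class = c("split_half_matrix", "matrix"))
}

# per-taste mean activation in odd and even runs over the roi columns
split_half_means <- function(patterns, cols, conditions) {
  odd <- patterns$run %% 2 == 1
  vals <- patterns$values[, cols, drop = FALSE]
  m <- function(sel) {
    sapply(conditions, function(cn) {
      idx <- sel & patterns$condition == cn
      if (!any(idx)) return(rep(NA_real_, length(cols)))
      colMeans(vals[idx, , drop = FALSE])
    })
  }
  counts <- sapply(conditions, function(cn)
    min(sum(odd & patterns$condition == cn), sum(!odd & patterns$condition == cn)))
  list(odd = m(odd), even = m(!odd), counts = counts)
}

#' Rank-order voxel activation profiles
#'
#' For each reference taste, voxels are sorted by descending even-run
#' activation (ties broken by voxel index) and the odd-run activation of
#' all tastes is read out along that order, averaged within percentile
#' bins so that profiles from regions of different sizes can be averaged
#' across subjects.  Taste-specific tuning shows as only the reference
#' taste's own curve starting high and falling; a shared response makes
#' all curves fall together.
#'
#' @inheritParams split_half_matrix
#' @param n_bins number of percentile bins along the rank axis.
#' @return numeric array `[reference taste, taste, bin]` of mean odd-run
#'   activation.
#' @export
rank_order_profile <- function(patterns, roi = NULL, conditions = NULL,
                               n_bins = 20) {
  cols <- roi_columns(patterns, roi)
  if (length(cols) < n_bins) stop("roi smaller than the number of rank bins")
  if (is.null(conditions)) conditions <- taste_conditions_of(patterns)
  halves <- split_half_means(patterns, cols, conditions)
  k <- length(conditions)
  out <- array(NA_real_, c(k, k, n_bins),
               dimnames = list(reference = conditions, taste = conditions, NULL))
  bins <- cut(seq_along(cols), breaks = n_bins, labels = FALSE)
  for (ref in seq_len(k)) {
    ord <- order(-halves$even[, ref], seq_along(cols))
    for (ta in seq_len(k)) {
      profile <- halves$odd[ord, ta]
      out[ref, ta, ] <- tapply(profile, bins, mean)
    }
  }
  out
}

#' Group statistics on split-half matrices
#'
#' Fisher z-transforms every cell of each subject's split-half matrix
#' and tests each cell against zero with a one-sample t-test across
#' subjects, Bonferroni-corrected over all cells of the matrix.  Also
#' reports the pooled same-taste vs different-taste contrast (paired t
#' on each subject's mean diagonal vs mean off-diagonal z).  Flags
#' follow the figure conventions: dagger for p < 0.05 uncorrected,
#' star for p < 0.05 Bonferroni-corrected.
#'
#' @param matrices list of [split_half_matrix()] objects, one per
#'   subject, sharing dimnames.
#' @return data.frame with one row per cell plus a `same_vs_diff` row;
#'   columns `odd`, `even`, `mean_r`, `mean_z`, `t`, `df`, `p`,
#'   `p_bonf`, `sig_unc`, `sig_corr`, `n_used`.
#' @export
same_diff_stats <- function(matrices) {
  stopifnot(length(matrices) >= 2)
  k <- nrow(matrices[[1]])
  conds <- rownames(matrices[[1]])
  zcap <- atanh(1 - 1e-12)
  zs <- lapply(matrices, function(m) {
    z <- atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12))
    pmin(pmax(z, -zcap), zcap)
  })
  n_cells <- k * k
  rows <- vector("list", n_cells + 1)
  ri <- 1
  for (a in seq_len(k)) for (b in seq_len(k)) {
    zv <- vapply(zs, function(z) z[a, b], numeric(1))
    rv <- vapply(matrices, function(m) m[a, b], numeric(1))
    ok <- is.finite(zv)
    tt <- one_sample_t(zv[ok])
    rows[[ri]] <- data.frame(odd = conds[a], even = conds[b],
                             mean_r = mean(rv[ok]), mean_z = mean(zv[ok]),
                             t = tt$t, df = tt$df, p = tt$p,
                             n_used = sum(ok))
    ri <- ri + 1
  }
  diff_z <- vapply(zs, function(z) {
    mean(diag(z), na.rm = TRUE) - mean(z[row(z) != col(z)], na.rm = TRUE)
  }, numeric(1))
  tt <- one_sample_t(diff_z[is.finite(diff_z)])
  rows[[ri]] <- data.frame(odd = "same", even = "diff",
                           mean_r = NA_real_, mean_z = mean(diff_z, na.rm = TRUE),
                           t = tt$t, df = tt$df, p = tt$p,
                           n_used = sum(is.finite(diff_z)))
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p * n_cells)
  out$p_bonf[ri] <- out$p[ri]  # pooled contrast is a single planned test
  out$sig_unc <- out$p < 0.05
  out$sig_corr <- out$p_bonf < 0.05
  rownames(out) <- NULL
  out
}

one_sample_t <- function(x) {
  n <- length(x)
  if (n < 2 || sd(x) == 0) {
    tstat <- if (n >= 2 && all(x == 0)) 0 else NA_real_
    return(list(t = tstat, df = n - 1,
                p = if (identical(tstat, 0)) 1 else NA_real_))
  }
  tstat <- mean(x) / (sd(x) / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), n - 1))
}

# resolve an roi argument into column indices of the pattern matrix
roi_columns <- function(patterns, roi) {
  nvox <- ncol(patterns$values)
  if (is.null(roi)) return(seq_len(nvox))
  if (is.array(roi)) {
    stopifnot(all(dim(roi) == patterns$grid$shape))
    return(which(roi[patterns$mask]))
  }
  if (is.logical(roi)) {
    stopifnot(length(roi) == nvox)
    return(which(roi))
  }
  stopifnot(all(roi >= 1), all(roi <= nvox))
  as.integer(roi)
}

taste_conditions_of <- function(patterns) {
  taste_labels(unique(patterns$condition))
}
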