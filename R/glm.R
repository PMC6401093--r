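#' Trial-wise GLM pattern extraction
#'
#' Models every stimulus presentation as a separate event: one regressor
#' per trial (boxcar convolved with the canonical HRF) entered
#' simultaneously in a single least-squares fit per voxel
#' (least-squares-all), alongside per-run intercept and linear-trend
#' nuisance terms.  Per-trial t-values are computed from the fit and
#' then demeaned per voxel across all trials, tasteless included.
#'
#' @param subject a `subject_dataset` generated in `"bold"` mode, or a
#'   volumes x voxel matrix (then `design`, `grid`, `mask`, `tr_s` are
#'   required).
#' @param design,grid,mask,tr_s needed only when `subject` is a bare
#'   matrix.
#' @param demean subtract the per-voxel mean t across trials (default).
#' @param stat carry `"t"` values forward (default) or raw `"beta"`
#'   amplitudes (useful for noiseless validation, where the residual
#'   variance degenerates and t-values are undefined).
#' @return a [trial_pattern_set()] of demeaned trial statistics.
#' @export
fit_trialwise <- function(subject, design = NULL, grid = NULL, mask = NULL,
                          tr_s = NULL, demean = TRUE, stat = c("t", "beta")) {
  stat <- match.arg(stat)
  if (inherits(subject, "subject_dataset")) {
    if (is.null(subject$bold)) stop("subject has no bold data; was it generated in patterns mode?")
    bold <- subject$bold
    design <- subject$design
    grid <- subject$grid
    mask <- subject$mask
    tr_s <- attr(design, "tr_s")
    ratings <- subject$ratings
  } else {
    bold <- subject
    ratings <- NULL
    if (is.null(design) || is.null(grid) || is.null(mask))
      stop("design, grid and mask are required with a bare bold matrix")
    if (is.null(tr_s)) tr_s <- attr(design, "tr_s")
  }
  X <- build_design_matrix(design, tr_s, trialwise = TRUE)
  fit <- glm_tstats(X$mat, bold, X$trial_cols)
  tvals <- if (stat == "t") fit$t else fit$beta
  if (demean) tvals <- sweep(tvals, 2, colMeans(tvals))
  trial_pattern_set(tvals, design$condition, design$run, grid, mask,
                    ratings = ratings, demeaned = demean)
}

#' Condition-level univariate contrast maps
#'
#' Fits one regressor per condition (all that condition's events share a
#' regressor) plus run nuisance terms, and optionally trial-modulated
#' positivity and negativity parametric regressors (mean-centred within
#' run before entry, to keep them orthogonal to the condition means).
#' Emits a taste-vs-baseline and a taste-vs-tasteless t-map per taste.
#'
#' @param subject a bold-mode `subject_dataset`.
#' @param include_valence add the hedonic rating modulators; requires
#'   ratings.
#' @param ratings optional override of the subject's ratings table.
#' @return list of `contrast_map` objects (fields `stat` - a 3D t-value
#'   array, `NA` outside the mask -, `contrast_name`,
#'   `valence_regressed`, `df`).
#' @export
fit_condition_contrasts <- function(subject, include_valence = FALSE,
                                    ratings = NULL) {
  stopifnot(inherits(subject, "subject_dataset"))
  if (is.null(subject$bold)) stop("subject has no bold data")
  design <- subject$design
  if (is.null(ratings)) ratings <- subject$ratings
  if (include_valence && is.null(ratings))
    stop("include_valence = TRUE requires per-trial ratings")
  tr_s <- attr(design, "tr_s")
  conds <- attr(design, "conditions")
  X <- build_design_matrix(design, tr_s, trialwise = FALSE,
                           ratings = if (include_valence) ratings else NULL)
  fit <- glm_qr(X$mat, subject$bold)
  tastes <- taste_labels(conds)
  tasteless <- setdiff(conds, tastes)
  maps <- list()
  for (ta in tastes) {
    cvb <- numeric(ncol(X$mat))
    cvb[X$cond_cols[ta]] <- 1
    maps[[paste0(ta, "_vs_baseline")]] <-
      contrast_map_from_fit(fit, cvb, paste0(ta, "_vs_baseline"),
                            include_valence, subject)
    if (length(tasteless)) {
      cvt <- cvb
      cvt[X$cond_cols[tasteless[1]]] <- -1
      maps[[paste0(ta, "_vs_tasteless")]] <-
        contrast_map_from_fit(fit, cvt, paste0(ta, "_vs_tasteless"),
                              include_valence, subject)
    }
  }
  maps
}

contrast_map_from_fit <- function(fit, cvec, name, valence_regressed, subject) {
  tv <- contrast_t(fit, cvec)
  vol <- array(NA_real_, subject$grid$shape)
  vol[subject$mask] <- tv
  structure(list(stat = vol, contrast_name = name,
                 valence_regressed = valence_regressed, df = fit$df),
            class = "contrast_map")
}

# Assemble the design matrix over all runs.  trialwise = TRUE gives one
# column per trial; otherwise one column per condition, plus optional
# run-centred positivity/negativity parametric modulators over all rated
# trials.  Per-run intercepts and linear trends are always appended.
build_design_matrix <- function(design, tr_s, trialwise, ratings = NULL) {
  nv <- attr(design, "n_vols_per_run")
  runs <- sort(unique(design$run))
  conds <- attr(design, "conditions")
  n_trials <- nrow(design)
  ncond <- length(conds)
  n_total <- nv * length(runs)
  ntask <- if (trialwise) n_trials else ncond
  mat <- matrix(0, n_total, ntask)
  pmod <- if (!is.null(ratings)) matrix(0, n_total, 2) else NULL
  for (r in runs) {
    sel <- which(design$run == r)
    R <- hrf_regressors(design$onset[sel], design$duration[sel], nv, tr_s)
    rows <- (which(runs == r) - 1) * nv + seq_len(nv)
    if (trialwise) {
      mat[rows, sel] <- R
    } else {
      for (ci in seq_along(conds)) {
        tc <- design$condition[sel] == conds[ci]
        if (any(tc)) mat[rows, ci] <- rowSums(R[, tc, drop = FALSE])
      }
    }
    if (!is.null(pmod)) {
      pos <- ratings$positivity[sel] - mean(ratings$positivity[sel])
      neg <- ratings$negativity[sel] - mean(ratings$negativity[sel])
      pmod[rows, 1] <- R %*% pos
      pmod[rows, 2] <- R %*% neg
    }
  }
  cond_cols <- if (!trialwise) stats::setNames(seq_along(conds), conds)
  if (!is.null(pmod)) {
    keep <- apply(pmod, 2, function(x) sd(x) > 1e-10)
    if (!all(keep))
      warning("constant valence modulator dropped (collinear with condition means)")
    pmod <- pmod[, keep, drop = FALSE]
    mat <- cbind(mat, pmod)
  }
  # per-run intercept + linear trend
  for (r in seq_along(runs)) {
    ic <- matrix(0, n_total, 2)
    rows <- (r - 1) * nv + seq_len(nv)
    ic[rows, 1] <- 1
    ic[rows, 2] <- seq_len(nv) / nv - mean(seq_len(nv) / nv)
    mat <- cbind(mat, ic)
  }
  list(mat = mat, trial_cols = seq_len(if (trialwise) n_trials else 0),
       cond_cols = cond_cols)
}

# QR-based multi-voxel OLS; returns coefficients, residual variance, df
# and the unscaled covariance diag factors
glm_qr <- function(X, Y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- qr_x$pivot[(qr_x$rank + 1):ncol(X)]
    stop("rank-deficient design matrix; offending columns: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qr_x, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - qr_x$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  list(beta = beta, sigma2 = sigma2, df = df, xtx_inv = xtx_inv)
}

contrast_t <- function(fit, cvec) {
  num <- drop(crossprod(cvec, fit$beta))
  den <- sqrt(drop(crossprod(cvec, fit$xtx_inv %*% cvec)) * fit$sigma2)
  num / den
}

# t-values (and raw betas) of the requested columns for every voxel
glm_tstats <- function(X, Y, cols) {
  fit <- glm_qr(X, Y)
  se_fac <- sqrt(diag(fit$xtx_inv)[cols])
  tvals <- fit$beta[cols, , drop = FALSE] /
    outer(se_fac, sqrt(fit$sigma2))
  list(t = tvals, beta = fit$beta[cols, , drop = FALSE], df = fit$df)
}
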