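#' Hedonic valence score
#'
#' Per-trial valence is the positivity rating minus the negativity
#' rating, so a taste can combine pleasant and unpleasant components
#' and still map onto a single signed scale.
#'
#' @param positivity,negativity ratings on a common scale.
#' @return numeric vector `positivity - negativity`.
#' @export
valence_score <- function(positivity, negativity) {
  stopifnot(length(positivity) == length(negativity))
  positivity - negativity
}

#' Neural representational dissimilarity matrix
#'
#' Pairwise-taste discriminability inside an independently defined ROI:
#' entry (a, b) is the leave-one-stimulus-pair-out LDA accuracy for
#' taste a vs taste b computed on the ROI voxels.  The matrix is
#' symmetric with `NaN` on the diagonal; group-level matrices are the
#' simple mean of per-subject matrices.
#'
#' @param patterns a [trial_pattern_set()].
#' @param roi as in [split_half_matrix()]; must come from an
#'   independent (e.g. leave-one-subject-out) definition for unbiased
#'   accuracies.
#' @param conditions conditions to include; defaults to the tastes.
#' @inheritParams pairwise_accuracy
#' @return object of class `taste_rdm` (fields `d`, `conditions`,
#'   `source = "neural"`); an empty ROI yields an all-`NaN` matrix with
#'   a warning.
#' @export
neural_rdm <- function(patterns, roi = NULL, conditions = NULL,
                       scheme = c("all-pairs", "matched"), shrinkage = 0) {
  scheme <- match.arg(scheme)
  if (is.null(conditions)) conditions <- taste_conditions_of(patterns)
  k <- length(conditions)
  cols <- tryCatch(roi_columns(patterns, roi), error = function(e) integer(0))
  if (!length(cols)) {
    warning("empty ROI: returning NaN dissimilarity matrix")
    d <- matrix(NaN, k, k, dimnames = list(conditions, conditions))
  } else {
    d <- pair_accuracy_matrix(patterns$values[, cols, drop = FALSE],
                              patterns$condition, classes = conditions,
                              scheme = scheme, shrinkage = shrinkage)
  }
  structure(list(d = d, conditions = conditions, source = "neural"),
            class = "taste_rdm")
}

#' Valence-based representational dissimilarity matrix
#'
#' Discriminates taste pairs from the one-dimensional per-trial valence
#' score alone (independent of any imaging data), using the same
#' leave-one-stimulus-pair-out LDA as the neural matrix.  In one
#' dimension the discriminant reduces to a threshold at the pooled
#' boundary between the class means.
#'
#' @param ratings data.frame with `positivity`, `negativity` and
#'   `condition` columns (as [sample_ratings()]), or a numeric valence
#'   vector if `labels` is given.
#' @param labels per-trial condition labels (taken from `ratings` if
#'   absent).
#' @param conditions conditions to include; defaults to the tastes.
#' @return object of class `taste_rdm` with `source = "valence"`.
#' @export
valence_rdm <- function(ratings, labels = NULL, conditions = NULL) {
  if (is.data.frame(ratings)) {
    v <- valence_score(ratings$positivity, ratings$negativity)
    if (is.null(labels)) labels <- ratings$condition
  } else v <- as.numeric(ratings)
  stopifnot(length(v) == length(labels))
  if (is.null(conditions)) conditions <- taste_labels(unique(labels))
  d <- pair_accuracy_matrix(matrix(v, ncol = 1), labels, classes = conditions,
                            scheme = "all-pairs", shrinkage = 0)
  structure(list(d = d, conditions = conditions, source = "valence"),
            class = "taste_rdm")
}

#' @export
print.taste_rdm <- function(x, ...) {
  cat("<taste_rdm source=", x$source, ">\n", sep = "")
  print(round(x$d, 3))
  invisible(x)
}

#' Relate neural discriminability to valence distance
#'
#' Pairs up the two dissimilarity matrices taste-pair by taste-pair and
#' reports the Spearman rank correlation between neural and
#' valence-based discriminability, with a permutation p-value obtained
#' by shuffling the pair labels.  A taste code that merely reflects
#' palatability would show a strong positive association; independence
#' shows none.
#'
#' @param neural,valence `taste_rdm` objects on the same condition set.
#' @param n_perm permutations for the p-value.
#' @param seed integer seed; `NULL` continues the RNG stream.
#' @return list with the per-pair `table` (columns `taste_a`, `taste_b`,
#'   `valence_acc`, `neural_acc`), `rho` and `p`; fewer than 3 pairs
#'   leaves the association undefined (`NA`).  A constant matrix on
#'   either side gives `rho = 0`, `p = 1`.
#' @export
accuracy_vs_valence <- function(neural, valence, n_perm = 10000, seed = NULL) {
  stopifnot(identical(neural$conditions, valence$conditions))
  k <- length(neural$conditions)
  ut <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  tab <- data.frame(taste_a = neural$conditions[ut[, 1]],
                    taste_b = neural$conditions[ut[, 2]],
                    valence_acc = valence$d[ut],
                    neural_acc = neural$d[ut])
  ok <- is.finite(tab$valence_acc) & is.finite(tab$neural_acc)
  if (sum(ok) < 3)
    return(list(table = tab, rho = NA_real_, p = NA_real_))
  x <- tab$valence_acc[ok]
  y <- tab$neural_acc[ok]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(table = tab, rho = 0, p = 1))
  rho <- cor(x, y, method = "spearman")
  use_seed(seed)
  rperm <- vapply(seq_len(n_perm), function(i) {
    cor(x, sample(y), method = "spearman")
  }, numeric(1))
  p <- (1 + sum(abs(rperm) >= abs(rho) - 1e-12)) / (1 + n_perm)
  list(table = tab, rho = rho, p = p)
}

#' Trial-pair similarity sorted by taste and valence congruence
#'
#' Correlates every unordered pair of trials' ROI activation patterns
#' (T trials give T(T-1)/2 coefficients; 4950 for the standard 100) and
#' sorts the pairs into the 2 x 2 categories of taste type (same,
#' different) x hedonic valence (same, different).  Continuous valence
#' scores are quantised to bins of `bin_width` slider units; two trials
#' share a valence level when their quantised scores are equal.
#'
#' @param patterns a [trial_pattern_set()] with ratings (or pass
#'   `valence`).
#' @param roi as in [split_half_matrix()].
#' @param valence optional per-trial valence scores overriding the
#'   ratings.
#' @param bin_width valence quantisation step (slider units).
#' @return object of class `similarity_cells`: `mean_r` and `n_pairs`
#'   are 2 x 2 matrices with rows `taste_same`/`taste_diff` and columns
#'   `val_same`/`val_diff`.
#' @export
similarity_cells <- function(patterns, roi = NULL, valence = NULL,
                             bin_width = 1) {
  cols <- roi_columns(patterns, roi)
  if (!length(cols)) stop("roi is empty")
  if (is.null(valence)) {
    if (is.null(patterns$ratings)) stop("no ratings available for valence sorting")
    valence <- valence_score(patterns$ratings$positivity,
                             patterns$ratings$negativity)
  }
  n <- nrow(patterns$values)
  stopifnot(length(valence) == n, bin_width > 0)
  C <- suppressWarnings(cor(t(patterns$values[, cols, drop = FALSE])))
  qv <- round(valence / bin_width)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  taste_same <- patterns$condition[ut[, 1]] == patterns$condition[ut[, 2]]
  val_same <- qv[ut[, 1]] == qv[ut[, 2]]
  r <- C[ut]
  dn <- list(c("taste_same", "taste_diff"), c("val_same", "val_diff"))
  mean_r <- matrix(NA_real_, 2, 2, dimnames = dn)
  n_pairs <- matrix(0L, 2, 2, dimnames = dn)
  for (ti in 1:2) for (vi in 1:2) {
    sel <- (taste_same == (ti == 1)) & (val_same == (vi == 1))
    n_pairs[ti, vi] <- sum(sel)
    if (any(sel)) mean_r[ti, vi] <- mean(r[sel], na.rm = TRUE)
  }
  structure(list(mean_r = mean_r, n_pairs = n_pairs, n_trials = n,
                 bin_width = bin_width),
            class = "similarity_cells")
}

#' Two-way repeated-measures ANOVA on similarity cells
#'
#' Tests the per-subject 2 x 2 cell means (taste same/different x
#' valence same/different) with a within-subject ANOVA: main effects
#' and interaction each on (1, n-1) degrees of freedom.  Levene's
#' homoscedasticity check across cells is reported alongside.  Subjects
#' with incomplete cells are dropped with a warning.
#'
#' @param cells list of [similarity_cells()] objects (one per subject),
#'   or a long data.frame with columns `subject`, `taste`, `valence`,
#'   `value`.
#' @return object of class `anova_2x2`: F statistics, p-values, df,
#'   `levene_p`, subject counts and the long data used.
#' @export
rm_anova_2x2 <- function(cells) {
  df <- if (is.data.frame(cells)) cells else cells_to_long(cells)
  stopifnot(all(c("subject", "taste", "valence", "value") %in% names(df)))
  bad <- tapply(is.finite(df$value), df$subject, function(x) !all(x) || length(x) < 4)
  drop_subj <- names(bad)[bad]
  if (length(drop_subj)) {
    warning("dropping ", length(drop_subj),
            " subject(s) with incomplete cells: ",
            paste(drop_subj, collapse = ", "))
    df <- df[!df$subject %in% drop_subj, , drop = FALSE]
  }
  n <- length(unique(df$subject))
  if (n < 3) stop("need at least 3 subjects with complete cells")
  df$subject <- factor(df$subject)
  df$taste <- factor(df$taste, levels = c("same", "diff"))
  df$valence <- factor(df$valence, levels = c("same", "diff"))
  fit <- aov(value ~ taste * valence + Error(subject / (taste * valence)),
             data = df)
  s <- summary(fit)
  pull <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)[1]
    Fv <- tab[i, "F value"]
    pv <- tab[i, "Pr(>F)"]
    # an exactly null effect (zero sum of squares up to round-off) is
    # F = 0 even when the residual is also degenerate
    if (is.finite(tab[i, "Sum Sq"]) && tab[i, "Sum Sq"] < 1e-20) {
      Fv <- 0
      pv <- 1
    }
    c(F = Fv, p = pv)
  }
  ft <- pull("Error: subject:taste", "taste")
  fv <- pull("Error: subject:valence", "valence")
  fi <- pull("Error: subject:taste:valence", "taste:valence")
  lev <- car::leveneTest(value ~ interaction(taste, valence), data = df)
  structure(list(F_taste = unname(ft["F"]), p_taste = unname(ft["p"]),
                 F_valence = unname(fv["F"]), p_valence = unname(fv["p"]),
                 F_interaction = unname(fi["F"]), p_interaction = unname(fi["p"]),
                 df = c(1L, n - 1L), levene_p = lev[1, "Pr(>F)"],
                 n_subjects = n, n_dropped = length(drop_subj), data = df),
            class = "anova_2x2")
}

#' @export
print.anova_2x2 <- function(x, ...) {
  cat(sprintf("<anova_2x2> n = %d, df = (%d, %d)\n", x$n_subjects,
              x$df[1], x$df[2]))
  cat(sprintf("  taste       F = %6.2f  p = %.4g\n", x$F_taste, x$p_taste))
  cat(sprintf("  valence     F = %6.2f  p = %.4g\n", x$F_valence, x$p_valence))
  cat(sprintf("  interaction F = %6.2f  p = %.4g\n", x$F_interaction,
              x$p_interaction))
  cat(sprintf("  Levene p = %.3g\n", x$levene_p))
  invisible(x)
}

cells_to_long <- function(cells) {
  do.call(rbind, lapply(seq_along(cells), function(s) {
    m <- cells[[s]]$mean_r
    data.frame(subject = paste0("S", s),
               taste = rep(c("same", "diff"), 2),
               valence = rep(c("same", "diff"), each = 2),
               value = c(m[1, 1], m[2, 1], m[1, 2], m[2, 2]))
  }))
}

#' Dependency-free similarity cells by randomised trial partition
#'
#' The standard 2 x 2 sort reuses each trial in many pairs, coupling
#' the cells.  This follow-up removes that dependency: each of
#' `n_draws` random draws assigns every trial to exactly one cell;
#' within a cell only trial pairs whose true taste/valence category
#' matches the cell are retained, so no trial (and hence no pair)
#' contributes to two cells.  The draw retained is the one maximising
#' the geometric mean of the cells' shares of all retained pairs -
#' by the AM-GM inequality, equal shares (1/4 each) score highest -
#' among draws leaving no cell empty.  If no draw is congruent, the
#' best available is used with a notice.
#'
#' @inheritParams similarity_cells
#' @param n_draws number of random cell assignments to search.
#' @param seed integer seed; `NULL` continues the RNG stream.
#' @return a [similarity_cells()]-like object with the extra fields
#'   `assignment` (per-trial cell, 1..4), `score` and `congruent`.
#' @export
independent_cells <- function(patterns, roi = NULL, valence = NULL,
                              n_draws = 10000, seed = NULL, bin_width = 1) {
  stopifnot(n_draws >= 1)
  cols <- roi_columns(patterns, roi)
  if (is.null(valence)) {
    if (is.null(patterns$ratings)) stop("no ratings available for valence sorting")
    valence <- valence_score(patterns$ratings$positivity,
                             patterns$ratings$negativity)
  }
  use_seed(seed)
  n <- nrow(patterns$values)
  qv <- round(valence / bin_width)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  taste_same <- patterns$condition[ut[, 1]] == patterns$condition[ut[, 2]]
  val_same <- qv[ut[, 1]] == qv[ut[, 2]]
  # cells numbered 0..3 = (taste_same, val_same), (taste_diff, val_same),
  # (taste_same, val_diff), (taste_diff, val_diff)
  pair_cat <- (!taste_same) + 2L * (!val_same)
  best <- best_cell_draw_cpp(ut[, 1] - 1L, ut[, 2] - 1L, pair_cat, n, n_draws)
  if (!best$congruent)
    message("no fully congruent draw found in ", n_draws,
            " draws; using the best available")
  assign <- best$assignment
  C <- suppressWarnings(cor(t(patterns$values[, cols, drop = FALSE])))
  r <- C[ut]
  in_cell <- assign[ut[, 1]] == assign[ut[, 2]] & assign[ut[, 1]] == pair_cat
  dn <- list(c("taste_same", "taste_diff"), c("val_same", "val_diff"))
  mean_r <- matrix(NA_real_, 2, 2, dimnames = dn)
  n_pairs <- matrix(0L, 2, 2, dimnames = dn)
  for (cc in 0:3) {
    sel <- in_cell & pair_cat == cc
    ti <- cc %% 2 + 1
    vi <- cc %/% 2 + 1
    n_pairs[ti, vi] <- sum(sel)
    if (any(sel)) mean_r[ti, vi] <- mean(r[sel], na.rm = TRUE)
  }
  structure(list(mean_r = mean_r, n_pairs = n_pairs, n_trials = n,
                 bin_width = bin_width, assignment = assign + 1L,
                 score = best$score, congruent = best$congruent),
            class = c("similarity_cells"))
}

#' Dependency-free 2 x 2 ANOVA across subjects
#'
#' Runs [independent_cells()] for every subject (each with its own
#' partition search) and submits the resulting per-subject cell means
#' to [rm_anova_2x2()].
#'
#' @param subjects list of [trial_pattern_set()] objects with ratings.
#' @param roi single ROI or list of per-subject ROIs.
#' @param n_draws,bin_width as [independent_cells()].
#' @param seed integer seed; subject s uses `seed + s`.
#' @return an `anova_2x2` with the per-subject `cells` attached.
#' @export
independent_cell_anova <- function(subjects, roi = NULL, n_draws = 10000,
                                   seed = NULL, bin_width = 1) {
  rois <- if (is.list(roi) && !is.array(roi)) roi else
    rep(list(roi), length(subjects))
  cells <- lapply(seq_along(subjects), function(s) {
    independent_cells(subjects[[s]], roi = rois[[s]], n_draws = n_draws,
                      seed = if (is.null(seed)) NULL else seed + s,
                      bin_width = bin_width)
  })
  out <- rm_anova_2x2(cells)
  out$cells <- cells
  out
}
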