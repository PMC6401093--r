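#' Pairwise LDA accuracy with leave-one-stimulus-pair-out CV
#'
#' Two-class linear discriminant classification with a
#' shrinkage-regularised pooled covariance.  Every fold holds out one
#' trial from each class and trains on the remaining ones (19 + 19 for
#' the standard 20-trial conditions); accuracy is the fraction of
#' held-out trials classified correctly, averaged over folds.  By
#' default all `n_a * n_b` cross-class pairs serve as folds; the
#' `"matched"` scheme pairs trial i with trial i (n folds).
#'
#' The pooled covariance is refit inside every training fold.  The
#' default (`shrinkage = 0`) is plain LDA - with 19 + 19 training
#' trials on a 33-voxel sphere the covariance is invertible, and an
#' exactly singular one (more features than training trials) falls back
#' to the minimum-norm pseudo-inverse rather than failing.  Shrinkage
#' toward the scaled identity is available as a fixed intensity in
#' `[0, 1]`, the Ledoit-Wolf analytic intensity estimated once per
#' class pair (`"lw"`), or the diagonal limit (`"diag"`).
#' Discriminant ties are deterministically assigned to the first class.
#'
#' @param x_a,x_b trial x feature matrices of the two classes (equal
#'   trial counts).
#' @param scheme `"all-pairs"` or `"matched"` fold enumeration.
#' @param shrinkage a number in `[0, 1]`, `"lw"`, or `"diag"`.
#' @return classification accuracy in `[0, 1]`.
#' @export
pairwise_accuracy <- function(x_a, x_b, scheme = c("all-pairs", "matched"),
                              shrinkage = 0) {
  scheme <- match.arg(scheme)
  x_a <- as.matrix(x_a)
  x_b <- as.matrix(x_b)
  lda_pair_cv_cpp(x_a, x_b, shrinkage_lambda(shrinkage),
                  matched = scheme == "matched")
}

#' All pairwise LDA accuracies among several classes
#'
#' Runs [pairwise_accuracy()] for every unordered pair of labels and
#' returns the symmetric accuracy matrix (diagonal `NaN`).
#'
#' @param x trial x feature matrix.
#' @param labels per-trial class labels.
#' @param classes class order for the output; defaults to the unique
#'   labels in order of appearance.
#' @inheritParams pairwise_accuracy
#' @return symmetric k x k accuracy matrix.
#' @export
pair_accuracy_matrix <- function(x, labels, classes = unique(labels),
                                 scheme = c("all-pairs", "matched"),
                                 shrinkage = 0) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  y <- match(labels, classes) - 1L
  keep <- !is.na(y)
  out <- pair_accuracy_matrix_cpp(x[keep, , drop = FALSE], y[keep],
                                  length(classes), shrinkage_lambda(shrinkage),
                                  matched = scheme == "matched")
  dimnames(out) <- list(classes, classes)
  out
}

shrinkage_lambda <- function(shrinkage) {
  if (is.numeric(shrinkage)) {
    stopifnot(shrinkage >= 0, shrinkage <= 1)
    return(shrinkage)
  }
  switch(match.arg(shrinkage, c("lw", "diag")), lw = -1, diag = 1)
}
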