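#!/usr/bin/env Rscript
# Split-half voxel-tuning analyses on two cohorts: one with a shared
# taste-unspecific response (the classic 3 T univariate picture) and
# one with taste-specific voxel tuning (the 7 T picture).  Odd/even-run
# correlation matrices, Fisher-z one-sample tests across subjects, and
# rank-order activation profiles.

source("analysis/00_settings.R")

run_cohort <- function(shared_frac, tag) {
  # the shared cohort needs a strong common response: demeaning across
  # conditions keeps only a fifth of a fully shared map
  model <- cohort_model(taste_amp = if (shared_frac == 1) 1 else 0.4,
                        shared_frac = shared_frac, valence_amp = 0)
  # analysed over the whole mock-insula mask on raw condition
  # activation: cross-condition demeaning would strip the shared
  # response these analyses are about
  mats <- lapply(seq_len(settings$n_subjects), function(s)
    split_half_matrix(cohort_subject(s, model, demean = FALSE)))
  tab <- same_diff_stats(mats)
  write.csv(tab, file.path(results_dir, sprintf("splithalf_%s.csv", tag)),
            row.names = FALSE)
  mean_mat <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  cells <- tab[tab$odd != "same", ]
  same <- cells$odd == cells$even
  cat(sprintf("\n[%s] mean same-taste r = %.3f, cross-taste r = %.3f\n", tag,
              mean(diag(mean_mat)), mean(mean_mat[row(mean_mat) != col(mean_mat)])))
  cat(sprintf("  Bonferroni-significant cells: %d/%d same-taste, %d/%d cross-taste\n",
              sum(cells$sig_corr[same]), sum(same),
              sum(cells$sig_corr[!same]), sum(!same)))
  pooled <- tab[tab$odd == "same" & tab$even == "diff", ]
  cat(sprintf("  pooled same-vs-different: t(%d) = %.2f, p = %.2g\n",
              pooled$df, pooled$t, pooled$p))

  prof <- Reduce(`+`, lapply(seq_len(settings$n_subjects), function(s)
    rank_order_profile(cohort_subject(s, model, demean = FALSE),
                       n_bins = 10))) / settings$n_subjects
  ref <- dimnames(prof)$reference[1]
  own <- prof[ref, ref, ]
  others <- colMeans(prof[ref, setdiff(dimnames(prof)$taste, ref), ])
  write.csv(data.frame(bin = seq_along(own), reference_taste = own,
                       other_tastes = others),
            file.path(results_dir, sprintf("rankorder_%s.csv", tag)),
            row.names = FALSE)
  invisible(tab)
}

cat("== shared (taste-unspecific) cohort: all tastes activate the same map ==\n")
run_cohort(shared_frac = 1, tag = "shared")
cat("\n== specific cohort: distinct orthogonal taste maps ==\n")
run_cohort(shared_frac = 0, tag = "specific")

cat("\nWith a shared map, odd/even correlations are uniformly positive",
    "(no voxel-level taste specificity); with planted taste-specific",
    "tuning the matrix diagonal dominates and survives Bonferroni,",
    "while cross-taste cells do not.\n")
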