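#!/usr/bin/env Rscript
# Validate the trial-wise GLM on simulated BOLD: noiseless recovery of
# the planted per-trial amplitudes, and the univariate valence control
# (a purely hedonic signal masquerades as a taste contrast until the
# rating regressors absorb it).

source("analysis/00_settings.R")

grid <- volume_grid(c(14L, 16L, 12L))  # BOLD simulation at reduced size
d <- build_design("exp1", n_runs = 2, trials_per_run = 10,
                  seed = settings$seed)

## 1. noiseless round trip ------------------------------------------------
m0 <- ground_truth_model(grid, noise_sd = 0)
su0 <- generate_subject(d, m0, mode = "bold", seed = settings$seed + 1)
pat0 <- fit_trialwise(su0, stat = "beta", demean = FALSE)
v <- valence_score(su0$ratings$positivity, su0$ratings$negativity)
planted <- t(m0$taste_patterns[, d$condition, drop = FALSE]) +
  gustotope:::valence_component(m0, v)
err <- max(abs(pat0$values - planted))
cat("noiseless BOLD -> trial-wise GLM: max |recovered - planted| =",
    format(err, digits = 3), "\n")

## 2. noisy t-value extraction --------------------------------------------
m1 <- ground_truth_model(grid, noise_sd = 0.5)
su1 <- generate_subject(d, m1, mode = "bold", seed = settings$seed + 2)
pat1 <- fit_trialwise(su1)
cat("noisy run: trial t-patterns", nrow(pat1$values), "x", ncol(pat1$values),
    "; per-voxel mean after demeaning =",
    format(max(abs(colMeans(pat1$values))), digits = 3), "\n")
write.csv(data.frame(check = c("noiseless_max_abs_error",
                               "demeaned_max_abs_colmean"),
                     value = c(err, max(abs(colMeans(pat1$values))))),
          file.path(results_dir, "glm_recovery.csv"), row.names = FALSE)

## 3. univariate valence control ------------------------------------------
m_val <- ground_truth_model(grid, taste_amp = 0, valence_amp = 0.15,
                            noise_sd = 0.5)
su2 <- generate_subject(d, m_val, mode = "bold", seed = settings$seed + 3)
with_v <- fit_condition_contrasts(su2, include_valence = TRUE)
without_v <- fit_condition_contrasts(su2, include_valence = FALSE)
vreg <- m_val$regions$valence
tab <- data.frame(
  contrast = "bitter_vs_tasteless",
  max_abs_t_without_valence = max(abs(without_v[["bitter_vs_tasteless"]]$stat[vreg]),
                                  na.rm = TRUE),
  max_abs_t_with_valence = max(abs(with_v[["bitter_vs_tasteless"]]$stat[vreg]),
                               na.rm = TRUE))
write.csv(tab, file.path(results_dir, "univariate_valence_control.csv"),
          row.names = FALSE)
cat("\nplanted hedonic-only signal, bitter-vs-tasteless peak |t| in the",
    "valence region:\n  without rating regressors:",
    round(tab$max_abs_t_without_valence, 1),
    "\n  with rating regressors:   ",
    round(tab$max_abs_t_with_valence, 1), "\n")
cat("The apparent 'bitter' activation is abolished once hedonic valence",
    "is controlled — a pure-valence code cannot pose as taste in the",
    "univariate model.\n")
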