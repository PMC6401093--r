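test_that("valence scoring is positivity minus negativity", {
  expect_equal(valence_score(7, 2), 5)
  expect_equal(valence_score(3.5, 3.5), 0)
  expect_equal(valence_score(0, 10), -10)
  expect_equal(valence_score(c(1, 2), c(2, 1)), c(-1, 1))
  expect_error(valence_score(1:3, 1:2))
})

test_that("valence-based discrimination hits the separable and null limits", {
  lab <- rep(c("sweet", "bitter"), each = 20)
  v_sep <- c(rnorm(20, 6, 0.5), rnorm(20, -6, 0.5))
  r <- valence_rdm(v_sep, lab)
  expect_equal(r$d["sweet", "bitter"], 1)
  set.seed(1)
  accs <- replicate(25, {
    v0 <- rnorm(40)
    valence_rdm(v0, lab)$d["sweet", "bitter"]
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("one-dimensional LDA reduces to the midpoint threshold rule", {
  threshold_cv <- function(va, vb) {
    n <- length(va)
    correct <- 0
    for (i in 1:n) for (j in 1:n) {
      ma <- mean(va[-i]); mb <- mean(vb[-j])
      mid <- (ma + mb) / 2
      up <- ma >= mb  # class a on the upper side
      pa <- if (up) va[i] >= mid else va[i] < mid
      # held-out b on the boundary resolves to class a (first class)
      pb <- if (up) vb[j] < mid else vb[j] >= mid
      correct <- correct + pa + pb
    }
    correct / (2 * n * n)
  }
  set.seed(2)
  lab <- rep(c("sour", "salty"), each = 15)
  for (rep in 1:6) {
    v <- c(rnorm(15, 0.8), rnorm(15))
    ours <- valence_rdm(v, lab)$d["sour", "salty"]
    expect_equal(ours, threshold_cv(v[1:15], v[16:30]))
  }
})

test_that("the neural RDM is symmetric, chance-calibrated and signal-sensitive", {
  pat <- noise_patterns(n_per_class = 12, p = 25, seed = 3)
  r <- neural_rdm(pat)
  expect_equal(r$d, t(r$d))
  expect_true(all(is.nan(diag(r$d))))
  off <- r$d[upper.tri(r$d)]
  expect_true(all(off >= 0 & off <= 1))
  expect_lt(abs(mean(off) - 0.5), 0.12)

  grid <- volume_grid(c(16, 20, 14))
  # whole-ROI decoding has more voxels than training df, so it runs in
  # the pseudo-inverse regime; plant a strong code and ask for clearly
  # above-chance discrimination of every pair
  m <- ground_truth_model(grid, taste_amp = 0.5, valence_amp = 0)
  d <- build_design("exp1", seed = 4)
  su <- generate_subject(d, m, mode = "patterns", seed = 4)
  r2 <- neural_rdm(demean_patterns(su$patterns), roi = m$regions$core)
  expect_true(all(r2$d[upper.tri(r2$d)] > 0.6))

  expect_warning(r3 <- neural_rdm(pat, roi = rep(FALSE, 25)), "empty ROI")
  expect_true(all(is.nan(r3$d)))
})

test_that("the neural-valence association detects monotone coupling and not constants", {
  conds <- c("sour", "sweet", "bitter", "salty")
  mk_rdm <- function(vals, source) {
    d <- matrix(NaN, 4, 4, dimnames = list(conds, conds))
    d[upper.tri(d)] <- vals
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    structure(list(d = d, conditions = conds, source = source),
              class = "taste_rdm")
  }
  v <- mk_rdm(seq(0.5, 0.95, length.out = 6), "valence")
  n_mono <- mk_rdm(seq(0.55, 0.9, length.out = 6), "neural")
  res <- accuracy_vs_valence(n_mono, v, n_perm = 500, seed = 5)
  expect_equal(res$rho, 1)
  expect_lt(res$p, 0.05)
  n_const <- mk_rdm(rep(0.7, 6), "neural")
  res2 <- accuracy_vs_valence(n_const, v, n_perm = 500, seed = 6)
  expect_equal(res2$rho, 0)
  expect_equal(res2$p, 1)
})

test_that("association is null for taste-only signal with scrambled valence", {
  grid <- volume_grid(c(14, 16, 12))
  m <- ground_truth_model(grid, taste_amp = 0.25, valence_amp = 0)
  d <- build_design("exp1", seed = 7)
  set.seed(8)
  rhos <- replicate(12, {
    su <- generate_subject(d, m, mode = "patterns", seed = sample.int(1e6, 1))
    nr <- neural_rdm(demean_patterns(su$patterns), roi = m$regions$core)
    scrambled <- su$ratings[sample(nrow(su$ratings)), ]
    scrambled$condition <- su$ratings$condition
    vr <- valence_rdm(scrambled, conditions = nr$conditions)
    accuracy_vs_valence(nr, vr, n_perm = 200, seed = 1)$rho
  })
  expect_lt(abs(mean(rhos)), 0.35)
})

test_that("similarity cells partition all T(T-1)/2 pairs", {
  grid <- tiny_grid()
  m <- ground_truth_model(grid)
  d <- build_design("exp1", seed = 9)
  su <- generate_subject(d, m, mode = "patterns", seed = 9)
  sc <- similarity_cells(demean_patterns(su$patterns), roi = m$regions$core)
  expect_equal(sum(sc$n_pairs), 4950)
  for (bw in c(0.5, 2)) {
    sc2 <- similarity_cells(su$patterns, roi = m$regions$core, bin_width = bw)
    expect_equal(sum(sc2$n_pairs), 4950)
  }
  pat <- noise_patterns(n_per_class = 7, p = 20, seed = 10)
  sc3 <- similarity_cells(pat, valence = rnorm(28))
  expect_equal(sum(sc3$n_pairs), 28 * 27 / 2)
})

test_that("identical trials correlate perfectly in every cell", {
  base <- rnorm(30)
  vals <- matrix(rep(base, each = 20), 20)
  pat <- flat_patterns(vals, rep(c("sour", "sweet"), 10), rep(1:2, 10))
  sc <- similarity_cells(pat, valence = rep(c(1, 5), 10))
  expect_true(all(abs(sc$mean_r[sc$n_pairs > 0] - 1) < 1e-12))
})

test_that("the repeated-measures ANOVA matches a subject-contrast oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(6:15, 1)
    cellmat <- matrix(rnorm(n * 4), n, 4)  # columns: ts.vs, td.vs, ts.vd, td.vd
    cells <- lapply(seq_len(n), function(s) {
      structure(list(mean_r = matrix(cellmat[s, ], 2, 2,
        dimnames = list(c("taste_same", "taste_diff"),
                        c("val_same", "val_diff"))),
        n_pairs = matrix(10L, 2, 2)), class = "similarity_cells")
    })
    an <- rm_anova_2x2(cells)
    oracle_f <- function(contrast) {
      cvals <- cellmat %*% contrast
      (mean(cvals) / (sd(cvals) / sqrt(n)))^2
    }
    expect_equal(an$F_taste, oracle_f(c(1, -1, 1, -1) / 2), tolerance = 1e-8)
    expect_equal(an$F_valence, oracle_f(c(1, 1, -1, -1) / 2), tolerance = 1e-8)
    expect_equal(an$F_interaction, oracle_f(c(1, -1, -1, 1)), tolerance = 1e-8)
    expect_equal(an$df, c(1L, n - 1L))
  }
})

test_that("the ANOVA is invariant to subject-wise constants and degenerate at equality", {
  set.seed(12)
  n <- 9
  cellmat <- matrix(rnorm(n * 4), n, 4)
  mk <- function(mat) lapply(seq_len(n), function(s) {
    structure(list(mean_r = matrix(mat[s, ], 2, 2,
      dimnames = list(c("taste_same", "taste_diff"), c("val_same", "val_diff"))),
      n_pairs = matrix(10L, 2, 2)), class = "similarity_cells")
  })
  a1 <- rm_anova_2x2(mk(cellmat))
  a2 <- rm_anova_2x2(mk(cellmat + rnorm(n) * 3))
  expect_equal(a1$F_taste, a2$F_taste, tolerance = 1e-8)
  expect_equal(a1$F_valence, a2$F_valence, tolerance = 1e-8)
  expect_equal(a1$F_interaction, a2$F_interaction, tolerance = 1e-8)

  flat <- mk(matrix(rep(rnorm(n), 4), n))  # equal cells within each subject
  a3 <- rm_anova_2x2(flat)
  expect_equal(a3$F_taste, 0)
  expect_equal(a3$p_taste, 1)
})

test_that("subjects with incomplete cells are dropped with a warning", {
  set.seed(13)
  cells <- lapply(1:5, function(s) {
    m <- matrix(rnorm(4), 2, 2,
                dimnames = list(c("taste_same", "taste_diff"),
                                c("val_same", "val_diff")))
    if (s == 2) m[1, 1] <- NaN
    structure(list(mean_r = m, n_pairs = matrix(10L, 2, 2)),
              class = "similarity_cells")
  })
  expect_warning(an <- rm_anova_2x2(cells), "incomplete")
  expect_equal(an$n_subjects, 4)
  expect_equal(an$n_dropped, 1)
})

test_that("independent cell draws keep cells disjoint and balanced-seeking", {
  grid <- tiny_grid()
  m <- ground_truth_model(grid, taste_amp = 0.2, valence_amp = 0)
  d <- build_design("exp1", seed = 14)
  su <- generate_subject(d, m, mode = "patterns", seed = 14)
  pat <- demean_patterns(su$patterns)
  ic <- independent_cells(pat, roi = m$regions$core, n_draws = 500, seed = 15)
  # hard independence contract: every trial sits in exactly one cell
  expect_equal(length(ic$assignment), 100)
  expect_true(all(ic$assignment %in% 1:4))
  # recompute retained pairs from the assignment: no trial in two cells
  v <- valence_score(su$ratings$positivity, su$ratings$negativity)
  qv <- round(v)
  ut <- which(upper.tri(matrix(0, 100, 100)), arr.ind = TRUE)
  cat_pair <- (!(pat$condition[ut[, 1]] == pat$condition[ut[, 2]])) +
    2L * (!(qv[ut[, 1]] == qv[ut[, 2]]))
  retained <- ic$assignment[ut[, 1]] == ic$assignment[ut[, 2]] &
    (ic$assignment[ut[, 1]] - 1L) == cat_pair
  expect_equal(sum(ic$n_pairs), sum(retained))
  trials_by_cell <- tapply(c(ut[retained, 1], ut[retained, 2]),
                           rep(ic$assignment[ut[retained, 1]], 2), unique)
  expect_equal(sum(lengths(trials_by_cell)),
               length(unique(unlist(trials_by_cell))))
  # AM-GM: the share-based score can never exceed 1/4
  expect_lte(ic$score, 0.25 + 1e-12)
  # a single draw still satisfies the partition contract
  ic1 <- independent_cells(pat, roi = m$regions$core, n_draws = 1, seed = 16)
  expect_equal(length(unique(ic1$assignment[1:100])), length(unique(ic1$assignment)))
})

test_that("the dependency-free ANOVA reaches the same conclusion as the standard one", {
  grid <- volume_grid(c(16, 20, 14))
  m <- ground_truth_model(grid, taste_amp = 0.25, valence_amp = 0)
  d <- build_design("exp1", seed = 17)
  subs <- lapply(1:10, function(s)
    demean_patterns(generate_subject(d, m, mode = "patterns",
                                     seed = 1700 + s)$patterns))
  std <- rm_anova_2x2(lapply(subs, similarity_cells, roi = m$regions$core))
  ind <- independent_cell_anova(subs, roi = m$regions$core, n_draws = 2000,
                                seed = 18)
  expect_lt(std$p_taste, 0.05)
  expect_lt(ind$p_taste, 0.05)
  expect_gt(ind$p_valence, 0.05)
  expect_gt(ind$p_interaction, 0.05)
})
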