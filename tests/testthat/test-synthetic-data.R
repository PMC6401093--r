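test_that("exp1 preset builds 100 trials balanced within and across runs", {
  d <- build_design("exp1", seed = 3)
  expect_s3_class(d, "event_design")
  expect_equal(nrow(d), 100)
  expect_equal(attr(d, "n_runs"), 5L)
  expect_equal(attr(d, "tr_s"), 2)
  expect_equal(attr(d, "n_vols_per_run"), 263L)
  counts <- table(d$condition)
  expect_true(all(counts == 20))
  per_run <- table(d$run, d$condition)
  expect_true(all(per_run == 4))
  for (r in 1:5) {
    on <- d$onset[d$run == r]
    expect_true(all(diff(on) > 0))
  }
})

test_that("exp2 preset carries the 7T timing and compound conditions", {
  d <- build_design("exp2", seed = 1)
  expect_equal(attr(d, "tr_s"), 0.5)
  expect_equal(attr(d, "n_vols_per_run"), 1010L)
  expect_setequal(unique(d$condition),
                  c("sweet1", "sweet2", "bitter1", "bitter2", "tasteless"))
  expect_true(all(d$duration == 2))
})

test_that("a minimal one-run design assigns one trial per condition", {
  d <- build_design("exp1", n_runs = 1, trials_per_run = 5, seed = 1)
  expect_equal(nrow(d), 5)
  expect_true(all(table(d$condition) == 1))
})

test_that("unbalanced trial counts are rejected", {
  expect_error(build_design("exp1", trials_per_run = 7), "balanced")
})

test_that("trial order is seed-deterministic", {
  d1 <- build_design("exp1", seed = 11)
  d2 <- build_design("exp1", seed = 11)
  d3 <- build_design("exp1", seed = 12)
  expect_identical(d1$condition, d2$condition)
  expect_false(identical(d1$condition, d3$condition))
})

test_that("ratings reduce to condition means at zero noise and vary otherwise", {
  grid <- tiny_grid()
  d <- tiny_design(seed = 2)
  m0 <- ground_truth_model(grid, rating_sd = 0)
  r0 <- sample_ratings(d, m0, seed = 1)
  mu <- m0$condition_valence_means[d$condition, ]
  expect_equal(r0$positivity, unname(mu[, 1]))
  expect_equal(r0$negativity, unname(mu[, 2]))

  m2 <- ground_truth_model(grid, rating_sd = 2)
  r2 <- sample_ratings(d, m2, seed = 1)
  within_var <- tapply(r2$positivity, r2$condition, var)
  expect_true(all(within_var > 0))
})

test_that("empirical rating means converge to the condition means", {
  # central means so slider clipping at 0/10 is negligible
  grid <- tiny_grid()
  conds <- design_preset("exp1")$conditions
  means <- matrix(c(5, 4), length(conds), 2, byrow = TRUE,
                  dimnames = list(conds, c("positivity", "negativity")))
  m <- ground_truth_model(grid, condition_valence_means = means, rating_sd = 1.5)
  d <- build_design("exp1", n_runs = 5, trials_per_run = 2000, seed = 4)
  r <- sample_ratings(d, m, seed = 9)
  # 2000 draws per condition: MC error ~ 1.5/sqrt(2000) ~ 0.034
  expect_true(all(abs(tapply(r$positivity, r$condition, mean) - 5) < 0.15))
  expect_true(all(abs(tapply(r$negativity, r$condition, mean) - 4) < 0.15))
})

test_that("noiseless pattern generation returns the planted maps exactly", {
  grid <- tiny_grid()
  m <- ground_truth_model(grid, noise_sd = 0)
  d <- tiny_design(seed = 5)
  su <- generate_subject(d, m, mode = "patterns", seed = 21)
  v <- valence_score(su$ratings$positivity, su$ratings$negativity)
  expected <- t(m$taste_patterns[, d$condition, drop = FALSE]) +
    gustotope:::valence_component(m, v)
  expect_equal(unname(su$patterns$values), unname(expected), tolerance = 1e-12)
})

test_that("generation is bit-identical under a fixed seed", {
  grid <- tiny_grid()
  m <- ground_truth_model(grid)
  d <- tiny_design(seed = 5)
  s1 <- generate_subject(d, m, mode = "patterns", seed = 33)
  s2 <- generate_subject(d, m, mode = "patterns", seed = 33)
  expect_identical(s1$patterns$values, s2$patterns$values)
  expect_identical(s1$ratings, s2$ratings)
})

test_that("an empty mask is rejected", {
  grid <- tiny_grid()
  expect_error(ground_truth_model(grid, mask = array(FALSE, grid$shape)),
               "empty")
})

test_that("a signal-free generator decodes at chance", {
  grid <- tiny_grid()
  m <- ground_truth_model(grid, taste_amp = 0, valence_amp = 0)
  d <- tiny_design(trials_per_run = 20, n_runs = 2, seed = 6)
  subj_means <- vapply(1:10, function(seed) {
    su <- generate_subject(d, m, mode = "patterns", seed = seed)
    pat <- demean_patterns(su$patterns)
    cols <- which(m$regions$core[m$mask])
    am <- pair_accuracy_matrix(pat$values[, cols], pat$condition)
    mean(am[upper.tri(am)])
  }, numeric(1))
  se <- sd(subj_means) / sqrt(length(subj_means))
  expect_lt(abs(mean(subj_means) - 0.5), max(3 * se, 0.02))
})

test_that("orthogonal layout plants mutually orthogonal equal-power maps", {
  grid <- volume_grid(c(20, 24, 18))
  m <- ground_truth_model(grid, taste_amp = 0.1)
  core_cols <- which(m$regions$core[m$mask])
  P <- m$taste_patterns[core_cols, taste_labels(m$conditions)]
  G <- crossprod(P)
  expect_equal(G, diag(diag(G)), tolerance = 1e-8, ignore_attr = TRUE)
  rms <- sqrt(colMeans(P^2))
  expect_equal(unname(rms), rep(0.1, 4), tolerance = 1e-8)
  expect_true(all(m$taste_patterns[, "tasteless"] == 0))
})
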