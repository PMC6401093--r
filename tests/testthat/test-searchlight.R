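# independent brute-force sphere enumeration
brute_count <- function(radius_mm, vox) {
  r <- ceiling(radius_mm / vox) + 1
  n <- 0
  for (x in -r:r) for (y in -r:r) for (z in -r:r)
    if ((x^2 + y^2 + z^2) * vox^2 <= radius_mm^2 + 1e-9) n <- n + 1
  n
}

test_that("sphere offsets match brute-force enumeration on 1/2/3 mm grids", {
  expect_equal(nrow(sphere_offsets(4, 2)$offsets), 33)
  expect_equal(nrow(sphere_offsets(2, 2)$offsets), 7)
  expect_equal(nrow(sphere_offsets(0, 2)$offsets), 1)
  for (vox in c(1, 2, 3)) {
    for (radius in seq(0, 10, by = 0.5)) {
      spec <- sphere_offsets(radius, vox)
      expect_equal(nrow(spec$offsets), brute_count(radius, vox),
                   info = sprintf("radius %.1f vox %d", radius, vox))
      expect_true(any(rowSums(abs(spec$offsets)) == 0))  # centre included
      expect_false(any(duplicated(spec$offsets)))
    }
  }
})

test_that("linearly separable noiseless clusters classify perfectly", {
  set.seed(1)
  Xa <- matrix(rnorm(20 * 5, sd = 0.1), 20) + 5
  Xb <- matrix(rnorm(20 * 5, sd = 0.1), 20) - 5
  expect_equal(pairwise_accuracy(Xa, Xb), 1)
  expect_equal(pairwise_accuracy(Xa, Xb, scheme = "matched"), 1)
})

test_that("accuracy sits at chance for shuffled labels on pure noise", {
  set.seed(2)
  accs <- replicate(40, {
    X <- matrix(rnorm(40 * 10), 40)
    lab <- sample(rep(c("a", "b"), each = 20))
    pairwise_accuracy(X[lab == "a", ], X[lab == "b", ])
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), max(3 * se, 0.02))
})

test_that("the CV engine agrees exactly with a plain-R reference", {
  ref_cv <- function(Xa, Xb, lam = 0) {
    na <- nrow(Xa); nb <- nrow(Xb); p <- ncol(Xa)
    correct <- 0
    for (i in 1:na) for (j in 1:nb) {
      Ta <- Xa[-i, , drop = FALSE]; Tb <- Xb[-j, , drop = FALSE]
      ma <- colMeans(Ta); mb <- colMeans(Tb)
      S <- (crossprod(sweep(Ta, 2, ma)) + crossprod(sweep(Tb, 2, mb))) /
        (na + nb - 4)
      Sig <- (1 - lam) * S + lam * mean(diag(S)) * diag(p)
      w <- solve(Sig, ma - mb)
      c0 <- sum(w * (ma + mb)) / 2
      correct <- correct + (sum(w * Xa[i, ]) - c0 >= 0) +
        (sum(w * Xb[j, ]) - c0 < 0)
    }
    correct / (2 * na * nb)
  }
  set.seed(3)
  for (rep in 1:6) {
    n <- sample(6:12, 1)
    p <- sample(2:(n - 3), 1)
    Xa <- matrix(rnorm(n * p), n) + 0.4
    Xb <- matrix(rnorm(n * p), n)
    expect_identical(pairwise_accuracy(Xa, Xb), ref_cv(Xa, Xb))
    expect_identical(pairwise_accuracy(Xa, Xb, shrinkage = 0.3),
                     ref_cv(Xa, Xb, 0.3))
  }
})

test_that("fold predictions match MASS::lda on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(4)
  n <- 12; p <- 4
  Xa <- matrix(rnorm(n * p), n) + 0.5
  Xb <- matrix(rnorm(n * p), n)
  ours <- pairwise_accuracy(Xa, Xb)
  correct <- 0
  for (i in 1:n) for (j in 1:n) {
    tr <- rbind(Xa[-i, ], Xb[-j, ])
    fit <- MASS::lda(tr, grouping = rep(c("a", "b"), each = n - 1))
    pr <- predict(fit, rbind(Xa[i, ], Xb[j, ]))$class
    correct <- correct + (pr[1] == "a") + (pr[2] == "b")
  }
  expect_equal(ours, correct / (2 * n * n))
})

test_that("pairwise accuracy obeys its invariances", {
  set.seed(5)
  Xa <- matrix(rnorm(15 * 8), 15) + 0.3
  Xb <- matrix(rnorm(15 * 8), 15)
  base <- pairwise_accuracy(Xa, Xb)
  # symmetry in class order
  expect_equal(pairwise_accuracy(Xb, Xa), base)
  # feature permutation
  perm <- sample(8)
  expect_equal(pairwise_accuracy(Xa[, perm], Xb[, perm]), base)
  # common constant added to every trial
  shift <- matrix(rnorm(8), 15, 8, byrow = TRUE)
  expect_equal(pairwise_accuracy(Xa + shift, Xb + shift), base,
               tolerance = 1e-12)
  # unequal class sizes are a hard error
  expect_error(pairwise_accuracy(Xa[1:10, ], Xb), "equal class sizes")
})

test_that("a singular covariance falls back to shrinkage/pseudo-inverse, not an error", {
  set.seed(6)
  Xa <- matrix(rnorm(5 * 20), 5) + 1   # far more features than trials
  Xb <- matrix(rnorm(5 * 20), 5)
  expect_no_error(a0 <- pairwise_accuracy(Xa, Xb))
  expect_no_error(a1 <- pairwise_accuracy(Xa, Xb, shrinkage = "lw"))
  expect_true(a0 >= 0 && a0 <= 1 && a1 >= 0 && a1 <= 1)
})

test_that("discriminability maps recover a planted single-taste region", {
  grid <- volume_grid(c(16, 20, 14))
  m <- ground_truth_model(grid, layout = "subregions", taste_amp = 0.6,
                          valence_amp = 0)
  d <- build_design("exp1", seed = 7)
  su <- generate_subject(d, m, mode = "patterns", seed = 7)
  maps <- discriminability_maps(demean_patterns(su$patterns))
  sweet_in <- mean(maps$sweet$acc[m$regions$sweet], na.rm = TRUE)
  expect_gt(sweet_in, 0.6)
  # the other tastes' own averages stay close to chance there
  for (ta in c("sour", "bitter", "salty")) {
    other <- mean(maps[[ta]]$acc[m$regions$sweet], na.rm = TRUE)
    expect_lt(other, sweet_in - 0.1)
  }
  # contract: all values bounded in [0, 1], NA outside the mask
  for (ta in names(maps)) {
    acc <- maps[[ta]]$acc
    expect_true(all(is.na(acc[!m$mask])))
    expect_true(all(acc[!is.na(acc)] >= 0 & acc[!is.na(acc)] <= 1))
    expect_equal(maps[[ta]]$chance, 0.5)
  }
})

test_that("all-zero patterns give exactly chance accuracy everywhere", {
  grid <- tiny_grid()
  m <- ground_truth_model(grid)
  pat <- trial_pattern_set(matrix(0, 50, sum(m$mask)),
                           rep(design_preset("exp1")$conditions, each = 10),
                           rep(1:2, 25), grid, m$mask)
  maps <- discriminability_maps(pat)
  for (ta in names(maps)) {
    vals <- maps[[ta]]$acc[!is.na(maps[[ta]]$acc)]
    expect_true(all(vals == 0.5))
  }
})

test_that("a mask smaller than one sphere is rejected", {
  grid <- tiny_grid()
  mask <- array(FALSE, grid$shape)
  mask[1:2, 1, 1] <- TRUE
  pat <- trial_pattern_set(matrix(rnorm(20 * 2), 20), rep(c("a", "b"), 10),
                           rep(1, 20), grid, mask)
  expect_error(discriminability_maps(pat), "smaller than one searchlight")
})

test_that("the per-voxel null accuracy distribution is centred at chance", {
  set.seed(8)
  accs <- replicate(220, {
    Xa <- matrix(rnorm(10 * 20), 10)
    Xb <- matrix(rnorm(10 * 20), 10)
    pairwise_accuracy(Xa, Xb)
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 2 * se + 0.005)
})

test_that("the null threshold behaves as a quantile should", {
  th <- subject_threshold(n_per_class = 10, n_features = 12, n_null = 300,
                          seed = 10)
  expect_lt(abs(mean(th$null_values) - 0.5), 0.02)
  expect_gt(th$threshold, 0.5)
  th_hi <- subject_threshold(n_per_class = 10, n_features = 12, alpha = 0.9999,
                             n_null = 300, seed = 10)
  expect_lte(th_hi$threshold, sort(th_hi$null_values)[2])
  expect_warning(subject_threshold(n_per_class = 6, n_features = 4, n_null = 50,
                                   seed = 1), "unstable")
})

test_that("the permutation null on real patterns is also centred at chance", {
  set.seed(11)
  X <- matrix(rnorm(100 * 33), 100)
  labels <- rep(design_preset("exp1")$conditions, each = 20)
  run <- rep(rep(1:5, each = 4), 5)
  th <- subject_threshold(null = "permutation", patterns = X, labels = labels,
                          run = run, n_null = 200, seed = 12)
  expect_lt(abs(mean(th$null_values) - 0.5), 0.02)
  expect_gt(th$threshold, 0.54)
})
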