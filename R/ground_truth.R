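#' Default per-condition hedonic rating means
#'
#' Mean positivity/negativity on the 0-10 slider scale for each
#' condition.  Sweet conditions are pleasant, bitter conditions
#' unpleasant, sour and salty intermediate, and the tasteless control
#' near-neutral and weak, reproducing the canonical association between
#' taste quality and palatability while leaving room for trial-by-trial
#' variation around the means.
#'
#' @param conditions character vector of condition labels.
#' @return numeric matrix, one row per condition, columns
#'   `positivity`/`negativity`.
#' @export
default_valence_means <- function(conditions = design_preset("exp1")$conditions) {
  tab <- rbind(sour = c(3, 5), sweet = c(7, 1), bitter = c(1, 7),
               salty = c(5, 3), tasteless = c(2, 2),
               sweet1 = c(7, 1), sweet2 = c(6.5, 1.5),
               bitter1 = c(1, 7), bitter2 = c(1.5, 6.5))
  unknown <- setdiff(conditions, rownames(tab))
  if (length(unknown))
    tab <- rbind(tab, matrix(c(4, 4), length(unknown), 2, byrow = TRUE,
                             dimnames = list(unknown, NULL)))
  out <- tab[conditions, , drop = FALSE]
  colnames(out) <- c("positivity", "negativity")
  out
}

#' Ground-truth generative model for a synthetic subject
#'
#' Specifies everything the synthetic-data generator needs: a mock
#' bilateral insula mask, one spatial amplitude map per taste condition,
#' a valence map whose trial amplitude scales with that trial's hedonic
#' valence score, the per-condition rating means, and the noise model
#' (white Gaussian, spatially smoothed, rescaled to unit variance
#' before scaling by `noise_sd`).
#'
#' Two spatial layouts are available.  The default, `"orthogonal"`,
#' plants a distinct fine-grained multivoxel pattern per taste inside a
#' shared bilateral "gustatory core" region - multi-taste population
#' coding in which every taste pair is discriminable at the same
#' voxels, the regime the conjunction analysis targets.  The patterns
#' are mutually orthogonal by construction; `shared_frac > 0` mixes in
#' a common taste-unspecific component (correlation `shared_frac`
#' between taste maps; `shared_frac = 1` is a purely shared activation
#' with no taste information, the classic univariate picture).
#' `"subregions"` instead assigns each taste its own disjoint sphere
#' pair strung along the anterior-posterior axis - a literal gustotopic
#' map with one taste per place.  Tasteless always maps to zero.
#'
#' The default `taste_amp` is calibrated so that, at the default noise
#' level, searchlight decoding inside the planted core runs at roughly
#' 75% taste-average accuracy - strong enough to recover, far from
#' ceiling.
#'
#' @param grid a [volume_grid()].
#' @param conditions condition labels; non-tasteless conditions get
#'   planted patterns, tasteless maps to zero.
#' @param mask logical array; defaults to [insula_mask()].
#' @param taste_amp per-voxel RMS amplitude of the planted taste maps
#'   (t-value units).
#' @param valence_amp amplitude of the valence map per unit of valence
#'   score (positivity - negativity, range -10..10).
#' @param region_radius_mm radius of the planted region spheres;
#'   defaults to a fraction of the mask's anterior-posterior semi-axis.
#' @param layout `"orthogonal"` (common multi-taste core) or
#'   `"subregions"` (one disjoint region per taste).
#' @param shared_frac fraction of map variance shared across tastes
#'   (orthogonal layout only).
#' @param condition_valence_means matrix as [default_valence_means()].
#' @param rating_sd trial-by-trial rating noise sd (slider units).
#' @param noise_sd pattern noise sd (t-value units).
#' @param noise_fwhm_mm spatial smoothness of the noise.
#' @param pattern_fwhm_mm spatial smoothness of the planted maps;
#'   defaults to the noise smoothness so the taste code has no
#'   artificial fine-scale spectral signature.
#' @param valence_code `"linear"`: one patterned map whose trial
#'   amplitude scales linearly with the valence score, so trial
#'   similarity follows the product `v_i * v_j`; `"tuning"`: a bank of
#'   `n_valence_channels` valence-tuned channel maps with Gaussian
#'   tuning curves, so trial similarity decays with `|v_i - v_j|`
#'   irrespective of sign.
#' @param n_valence_channels channels for the tuning code.
#' @param pattern_seed seed for the deterministic construction of the
#'   planted patterns (kept separate from subject seeds so that all
#'   subjects share one ground truth).
#' @return object of class `ground_truth_model` with fields including
#'   `taste_patterns` (mask-voxel x condition matrix), `valence_pattern`
#'   and `regions` (named list of logical arrays: one per taste, `core`
#'   for their union, `valence`).
#' @export
ground_truth_model <- function(grid = volume_grid(), conditions = design_preset("exp1")$conditions,
                               mask = NULL, taste_amp = 0.08, valence_amp = 0.06,
                               region_radius_mm = NULL,
                               layout = c("orthogonal", "subregions"),
                               shared_frac = 0,
                               condition_valence_means = NULL,
                               rating_sd = 1.5, noise_sd = 1, noise_fwhm_mm = 6,
                               pattern_fwhm_mm = noise_fwhm_mm,
                               valence_code = c("linear", "tuning"),
                               n_valence_channels = 8,
                               pattern_seed = 1) {
  valence_code <- match.arg(valence_code)
  layout <- match.arg(layout)
  stopifnot(rating_sd >= 0, noise_sd >= 0, noise_fwhm_mm >= 0,
            shared_frac >= 0, shared_frac <= 1)
  if (is.null(mask)) mask <- insula_mask(grid)
  if (!any(mask)) stop("mask is empty")
  if (is.null(condition_valence_means))
    condition_valence_means <- default_valence_means(conditions)
  stopifnot(all(conditions %in% rownames(condition_valence_means)))

  tastes <- taste_labels(conditions)
  shp <- grid$shape
  ctr <- (shp + 1) / 2
  semi_y_vox <- 0.25 * shp[2]
  semi_y_mm <- semi_y_vox * grid$voxel_size_mm[2]
  cx <- 0.28 * shp[1]
  bilateral <- function(y_off_vox, radius) {
    reg <- array(FALSE, shp)
    for (sgn in c(-1, 1))
      reg <- reg | sphere_region(grid, c(ctr[1] + sgn * cx, ctr[2] + y_off_vox,
                                         ctr[3]), radius)
    reg & mask
  }

  nvox <- sum(mask)
  regions <- list()
  taste_patterns <- matrix(0, nvox, length(conditions),
                           dimnames = list(NULL, conditions))
  if (layout == "orthogonal") {
    if (is.null(region_radius_mm)) region_radius_mm <- 0.35 * semi_y_mm
    core <- bilateral(0, region_radius_mm)
    ncore <- sum(core[mask])
    if (ncore <= length(tastes))
      stop("core region too small for orthogonal taste patterns")
    raw <- planted_basis_maps(shp, length(tastes) + 1 + n_valence_channels,
                              pattern_seed, pattern_fwhm_mm,
                              grid$voxel_size_mm)
    basis <- raw[as.vector(core), seq_len(length(tastes) + 1), drop = FALSE]
    # the shared (taste-unspecific) component is a uniform positive
    # activation of the core - an activation blob, not a pattern - and
    # the taste-specific maps are orthogonalised against it, so they
    # carry identity in zero-mean spatial texture
    basis[, 1] <- 1
    z <- qr.Q(qr(basis))
    if (sum(z[, 1]) < 0) z[, 1] <- -z[, 1]
    scale <- taste_amp * sqrt(ncore)
    for (i in seq_along(tastes)) {
      v <- sqrt(shared_frac) * z[, 1] + sqrt(1 - shared_frac) * z[, i + 1]
      taste_patterns[core[mask], tastes[i]] <- scale * v
      regions[[tastes[i]]] <- core
    }
    regions[["core"]] <- core
  } else {
    if (is.null(region_radius_mm)) region_radius_mm <- 0.25 * semi_y_mm
    fr <- (seq_along(tastes) - (length(tastes) + 1) / 2) * 0.5
    for (i in seq_along(tastes)) {
      reg <- bilateral(fr[i] * semi_y_vox, region_radius_mm)
      regions[[tastes[i]]] <- reg
      taste_patterns[, tastes[i]] <- taste_amp * as.numeric(reg[mask])
    }
    regions[["core"]] <- Reduce(`|`, regions[tastes])
    raw <- planted_basis_maps(shp, length(tastes) + 1 + n_valence_channels,
                              pattern_seed, pattern_fwhm_mm,
                              grid$voxel_size_mm)
  }
  # valence region: dorsal sphere pair, clear of the taste regions.
  # The valence map is itself spatially patterned (a smooth random map,
  # unit per-voxel RMS, scaled by valence_amp): a spatially uniform map
  # would vanish under the across-voxel centring of pattern
  # correlations and could never be seen by similarity analyses.
  vreg <- array(FALSE, shp)
  for (sgn in c(-1, 1)) {
    cen <- c(ctr[1] + sgn * cx, ctr[2], ctr[3] + 0.45 * 0.18 * shp[3] * 2)
    vreg <- vreg | sphere_region(grid, cen, region_radius_mm)
  }
  vreg <- vreg & mask
  regions[["valence"]] <- vreg
  valence_pattern <- numeric(nvox)
  valence_channels <- NULL
  channel_centers <- NULL
  nvreg <- sum(vreg)
  if (nvreg > 0) {
    vcols <- raw[as.vector(vreg), length(tastes) + 1 + seq_len(n_valence_channels),
                 drop = FALSE]
    if (valence_code == "linear") {
      vmap <- vcols[, 1]
      vmap <- vmap / sqrt(mean(vmap^2))
      valence_pattern[vreg[mask]] <- valence_amp * vmap
    } else {
      # valence tuning channels: orthonormal maps, one per preferred
      # valence level; trial similarity then decays with |v_i - v_j|
      # irrespective of sign
      if (nvreg < n_valence_channels)
        stop("valence region too small for the tuning-channel code")
      q <- qr.Q(qr(vcols))
      valence_channels <- matrix(0, nvox, n_valence_channels)
      valence_channels[vreg[mask], ] <- valence_amp * sqrt(nvreg) * q
      channel_centers <- seq(-9, 9, length.out = n_valence_channels)
    }
  }

  structure(list(grid = grid, mask = mask, conditions = conditions,
                 taste_patterns = taste_patterns,
                 valence_pattern = valence_pattern,
                 valence_code = valence_code,
                 valence_channels = valence_channels,
                 channel_centers = channel_centers, regions = regions,
                 condition_valence_means = condition_valence_means,
                 taste_amp = taste_amp, valence_amp = valence_amp,
                 layout = layout, shared_frac = shared_frac,
                 region_radius_mm = region_radius_mm,
                 rating_sd = rating_sd, noise_sd = noise_sd,
                 noise_fwhm_mm = noise_fwhm_mm, pattern_seed = pattern_seed),
            class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat("<ground_truth_model> ", sum(x$mask), " mask voxels, ",
      length(taste_labels(x$conditions)), " planted taste regions (",
      x$layout, "), taste_amp ", x$taste_amp, ", valence_amp ",
      x$valence_amp, ", noise_sd ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

# per-trial valence signal component: n_trials x mask-voxel matrix
valence_component <- function(model, v) {
  if (model$valence_code == "linear" || is.null(model$valence_channels))
    return(outer(v, model$valence_pattern))
  ctr <- model$channel_centers
  sigma <- ctr[2] - ctr[1]
  act <- exp(-outer(v, ctr, `-`)^2 / (2 * sigma^2))
  act <- act / sqrt(rowSums(act^2))
  act %*% t(model$valence_channels)
}

# deterministic smooth random basis maps over the grid (one column per
# map), leaving the caller's RNG stream untouched
planted_basis_maps <- function(shp, n_maps, pattern_seed, fwhm_mm,
                               voxel_size_mm) {
  old_seed <- get0(".Random.seed", globalenv())
  set.seed(as.integer(pattern_seed))
  raw <- matrix(rnorm(prod(shp) * n_maps), prod(shp))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  batch_smooth(raw, shp, fwhm_mm, voxel_size_mm)
}

#' Sample per-trial hedonic ratings
#'
#' Draws each trial's positivity and negativity around its condition
#' mean with sd `rating_sd`, clipped to the 0-10 slider range (real
#' sliders pin at the scale ends).  `rating_sd = 0` returns the
#' condition means exactly.
#'
#' @param design an [build_design()] event design.
#' @param model a [ground_truth_model()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return data.frame with columns `trial`, `run`, `condition`,
#'   `positivity`, `negativity`.
#' @export
sample_ratings <- function(design, model, seed = NULL) {
  use_seed(seed)
  mu <- model$condition_valence_means[design$condition, , drop = FALSE]
  n <- nrow(design)
  pos <- pmin(10, pmax(0, mu[, 1] + rnorm(n, sd = model$rating_sd)))
  neg <- pmin(10, pmax(0, mu[, 2] + rnorm(n, sd = model$rating_sd)))
  data.frame(trial = seq_len(n), run = design$run, condition = design$condition,
             positivity = pos, negativity = neg)
}
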