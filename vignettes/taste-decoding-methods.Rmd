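---
title: "Decoding taste quality from multivoxel patterns: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding taste quality from multivoxel patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gustotope)
```

## The scientific problem

Human gustatory cortex has resisted the kind of mapping that gave vision
its retinotopy and audition its tonotopy.  Voxel-wise univariate
contrasts of basic tastes (sweet, sour, bitter, salty) against a
tasteless control tend to show overlapping, individually variable
activation in the insula, and what survives often tracks *palatability*
— how pleasant or unpleasant the experience was — rather than taste
quality itself.  The analytical programme implemented here asks whether
taste quality is carried instead by fine-grained *multivoxel patterns*:
local activity patterns that discriminate every pair of basic tastes,
over and above the hedonic response.

The pipeline runs, end to end, on synthetic data with known ground
truth: pattern extraction (trial-wise GLM), split-half univariate
tuning analyses, searchlight linear-discriminant decoding, sign-flip
permutation group inference with familywise-error (FWE) control,
four-taste conjunction mapping, and representational analyses that pit
taste type against hedonic valence.

## The session model

A session follows the 3 T protocol: five runs of twenty trials, 100
taste-solution deliveries in total, with the five conditions (four
tastes plus tasteless) balanced within every run (four trials each).
Trials are spaced 26 s apart (1244 ms delivery, swallow cue, rating
scales, rinse), giving 263 volumes per run at TR = 2 s; the 7 T variant
(`exp2`) uses 25 s spacing, 2 s delivery and 1010 volumes at
TR = 0.5 s.  After each trial the subject rates positivity and
negativity on separate sliders; the signed hedonic *valence score* of a
trial is positivity − negativity.

`build_design()` produces these event tables with a seeded per-run
permutation of condition order; `sample_ratings()` draws each trial's
ratings around its condition's mean (sweet pleasant, bitter unpleasant,
sour/salty intermediate, tasteless weak and neutral) with sd
`rating_sd` (default 1.5 slider units), clipped to the 0–10 scale the
way physical sliders pin at their ends.  The within-condition rating
variance is a free parameter of the generator — the protocol defines
the scales but not the variance — and 1.5 units gives every condition
overlapping valence distributions while preserving the canonical
ordering, which is the regime in which disentangling taste from
valence is non-trivial and interesting.

## The generative ground-truth model

`ground_truth_model()` plants known structure on a mock anatomy:

* **Mask.** Two mirrored ellipsoids on the analysis grid stand in for
  the bilateral insula.  Sizes scale with the grid, so the same model
  runs on the full 40×48×36 grid (2 mm isotropic) or a down-sampled
  one.
* **Taste code.** The default `"orthogonal"` layout places a distinct
  multivoxel pattern per taste on a shared bilateral *core* region —
  multi-taste population coding, the regime in which one region
  discriminates all taste pairs and the four-taste conjunction is
  non-empty.  Patterns are smooth random maps (FWHM matched to the
  noise, see below), orthonormalised and scaled to a per-voxel RMS
  amplitude `taste_amp`; `shared_frac` mixes in a common
  taste-unspecific component (at `shared_frac = 1` the code carries no
  taste information at all — the classic univariate picture).  That
  shared component is a uniform positive activation of the core — an
  activation blob, the thing a univariate contrast sees — while the
  taste-specific maps are orthogonalised against it and carry identity
  in zero-mean spatial texture.  The
  `"subregions"` layout instead gives each taste its own disjoint
  sphere pair, a literal one-taste-one-place gustotopic map: useful for
  single-taste recovery checks, but note that under this layout a
  four-taste conjunction is empty *by construction*, because a voxel
  inside one taste's sphere supports only that taste's pairwise
  discriminations.
* **Valence code.** A separate dorsal region carries the hedonic
  signal.  Under the default `"linear"` code one spatially patterned
  map is scaled by each trial's valence score.  A spatially *uniform*
  map would be useless here: pattern correlations centre each trial's
  values across voxels, so a constant map contributes exactly nothing
  to trial-pair similarity.  The `"tuning"` code instead uses a bank
  of valence-tuned channel maps (Gaussian tuning curves over the
  valence axis, activation vector normalised per trial), which makes
  trial-pair similarity decay with |v_i − v_j| irrespective of sign —
  the two codes differ in exactly the property the 2×2 similarity
  analysis is sensitive to (see *Limits* below).
* **Noise.** White Gaussian noise per trial (or per volume in BOLD
  mode), spatially smoothed to `noise_fwhm_mm` (default 6 mm) and
  rescaled to unit variance before scaling by `noise_sd`, mimicking
  the spatial autocorrelation of real residuals.

Planted maps are smoothed to the *same* FWHM as the noise by default.
This matters: fine-grained (white) planted patterns under smooth noise
hand the whitening LDA an unrealistic spectral shortcut — near-ceiling
decoding at amplitudes that are invisible to correlation-based
analyses — whereas matched smoothness makes decoding accuracy and
pattern-similarity effects rise and fall together, as they do in real
data.

The default `taste_amp = 0.08` (t-value units per voxel, RMS) was
fixed once by a coarse calibration so that searchlight decoding inside
the planted core runs at ≈75% taste-average accuracy at the default
noise level — clearly above chance, clearly below ceiling.

`generate_subject()` emits either direct trial×voxel patterns (the
fast path used throughout the analyses) or full BOLD time series:
per-trial amplitudes convolved with a canonical double-gamma HRF (peak
6 s, undershoot 16 s, peak:undershoot 6:1, unit peak), plus baseline,
per-run linear drift and smooth noise.

## Pattern extraction

`fit_trialwise()` models every stimulus presentation as its own
regressor, entered simultaneously in one least-squares fit per voxel
("least-squares-all"), with per-run intercepts and linear trends as
nuisance terms.  Per-trial t-values are demeaned per voxel across all
trials (tasteless included).  The alternative reading — one design per
trial — was not adopted: with 26 s spacing the regressors are nearly
orthogonal and the single-design fit is the simplest faithful model.
On noiseless input the recovered betas equal the planted amplitudes to
machine precision (the t-statistic is undefined without residual
variance, so validation uses `stat = "beta"`).

`fit_condition_contrasts()` fits one regressor per condition, plus —
when requested — trial-modulated positivity and negativity parametric
regressors, mean-centred within run so they stay orthogonal to the
condition means.  This is the univariate valence control: a planted
hedonic-only signal produces a strong bitter-vs-tasteless "activation"
that disappears once the rating modulators absorb it.

## Univariate tuning analyses

These analyses run on *raw* condition activation over the whole mask,
not on the cross-condition demeaned patterns used for decoding:
demeaning across the five conditions removes four fifths of a shared
activation (all of it if tasteless shared it too) and couples the two
halves negatively through the grand mean, which would hide the
taste-unspecific picture by construction.  Runs are split by index
(1, 3, 5 vs 2, 4) — a run-wise reliability split, not a trial-parity
one.  `split_half_matrix()` correlates each
taste's mean activation profile in the odd runs with every taste's
profile in the even runs; `rank_order_profile()` sorts voxels by
even-run activation (ties broken by voxel index) and reads out odd-run
activation along that order, averaged in 20 percentile bins so
profiles from ROIs of different sizes can be averaged across subjects.
`same_diff_stats()` Fisher-z-transforms each cell, tests it against
zero across subjects, and Bonferroni-corrects over all k×k cells of
the matrix (the family is the full matrix; the pooled same-vs-different
contrast is a single planned test and is reported uncorrected).

## Searchlight decoding

`sphere_offsets()` enumerates all lattice offsets within the radius —
exactly 33 voxels for a 4 mm radius on a 2 mm grid.  At every mask
voxel the sphere's trial patterns feed pairwise two-class LDA with
leave-one-stimulus-pair-out cross-validation: each fold holds out one
trial of each class and trains on the remaining 19 + 19.  All 20×20
cross-class pairs serve as folds by default (the index-matched 20-fold
scheme is available via `scheme = "matched"`); each taste's
discriminability is its accuracy averaged over the four comparisons
with the other conditions, tasteless included.

**Classifier regularisation.**  The default is plain LDA — the pooled
covariance is refit in every training fold, and with 38 training
trials on 33 features it is invertible.  Fixed shrinkage toward the
scaled identity, the analytic Ledoit–Wolf intensity (estimated once
per class pair) and diagonal LDA are available options, and an exactly
singular covariance (more features than trials, as can happen for
whole-ROI decoding) falls back to the minimum-norm pseudo-inverse
rather than failing.  Plain LDA was chosen as the default because it
is the plainest reading of "an LDA classifier" *and* because it is the
variant whose null behaviour matches the published single-subject
operating point: the 95th percentile of the null distribution of
taste-average accuracy under the standard geometry comes out at
≈58.5%, against ≈60% under moderate-to-analytic shrinkage (on null
data the Ledoit–Wolf intensity is ≈0.93, i.e. near-diagonal LDA).
Discriminant ties (score exactly zero) go deterministically to the
first class in label order.  Spheres that exit the mask keep their
in-mask voxels if at least half the sphere remains, else the voxel is
NA.

`subject_threshold()` builds that null distribution explicitly —
fresh Gaussian patterns per realisation, or label permutation within
run on supplied patterns — and returns its upper quantile: the
accuracy a single subject's sphere must exceed for p < 0.05
uncorrected.

For speed, the fold loop exploits the algebra of the leave-one-pair-out
scheme: the fold covariance differs from the full pooled scatter by two
symmetric rank-one downdates, so each fold's discriminant comes from
the precomputed full inverse by two Sherman–Morrison steps (O(p) per
fold) — bit-identical to the direct per-fold solve, which remains as
the fallback for near-singular downdates and for non-zero shrinkage.

## Group inference

`signflip_onesample()` implements the one-sample max-statistic
permutation test: subject accuracy maps are smoothed (4 mm FWHM,
kernel renormalised inside the mask), centred at chance (50%), and the
per-voxel one-sample t is referred to the distribution of the maximal
t over the mask under random sign flips of whole subjects
(n_perm = 10,000 by default).  The FWE threshold is the 95th
percentile of that max-t distribution; corrected p-values use the
(b+1)/(m+1) convention, which is valid by construction.  When
2^n_subjects ≤ n_perm the full flip set is enumerated instead and
p-values are exact.  Degenerate voxels: all-zero data give NaN and are
excluded from the max; constant non-zero data give ±Inf (an
infinitely consistent effect) — the exhaustive enumeration then yields
the minimal attainable p of 1/2^n.

`conjunction_count()` counts, per voxel, the tastes whose observed t
exceeds their own FWE threshold — valid conjunction inference requires
significance in *all* component tests, and the count-4 stratum is the
multi-taste region.  When judging recovery of a planted code, the
natural target for any searchlight statistic is the planted region
*dilated by the sphere radius*: a sphere centred just outside the code
still reaches into it and is genuinely discriminative there, so the
recovered conjunction matches the dilated core (Dice ≈ 0.9), not the
bare core.  `loso_overlap()` repeats the conjunction with
each subject left out, yielding per-fold ROIs whose definition is
independent of the left-out subject's data (asserted by test), plus
the percentage-overlap volume across folds.

## Representational analyses

Inside the independently defined ROI, `neural_rdm()` computes the
leave-one-pair-out LDA accuracy for every taste pair — a
representational dissimilarity matrix with accuracy as the distance —
and `valence_rdm()` does the same from the one-dimensional valence
score alone (where LDA reduces to a midpoint threshold rule; an
exhaustive threshold-sweep oracle verifies this in the tests).
`accuracy_vs_valence()` relates the two matrices pair by pair with a
Spearman rank correlation and a pair-label permutation p-value.  The
group matrix is the simple mean of per-subject matrices, and the
default condition set for RDMs is the four tastes (tasteless excluded;
include it via `conditions`).

`similarity_cells()` correlates every unordered pair of the 100
trials' ROI patterns (4950 coefficients) and sorts the pairs into the
2×2 categories of taste type (same/different) × valence
(same/different).  "Same valence" for continuous scores means equal
after quantisation to `bin_width` slider units (default 1) — the
discrete-slider reading, and the analysis's most consequential free
choice: coarser bins blur the valence factor, finer bins empty its
cells.  `rm_anova_2x2()` runs the within-subject 2×2 ANOVA (each
effect on (1, n−1) degrees of freedom) with Levene's homoscedasticity
check reported alongside; its F-values are verified against a
subject-contrast t² oracle to 1e-8.

Because the same trial enters many pairs, the four cells are not
independent.  `independent_cells()` removes the dependency: each of
`n_draws` random draws assigns every trial to exactly one cell; within
a cell only pairs whose true category matches the cell are retained,
so no trial contributes to two cells.  The retained draw maximises the
geometric mean of the cells' shares of all retained pairs — by the
AM–GM inequality equal shares (¼ each) score highest — among draws
that leave no cell empty.  The default search is 10,000 draws
(configurable; the analysis is insensitive to this once all cells are
populated, since the ANOVA conclusions, not the scores, are the
output).

## Limits of the disentanglement, by design

Two structural facts about the 2×2 similarity analysis emerged from
the generator and are worth stating plainly:

* A **spatially uniform** valence map can never register in the
  similarity analysis (across-voxel centring annihilates it), and a
  **linear** rank-one valence code registers through the *product*
  v_i·v_j.  Because taste determines mean valence, that product is
  taste-predictive, so under a linear valence-only code the ANOVA
  shows a taste effect that no amount of valence binning removes.
  The "does a pure valence code masquerade as taste?" question is
  therefore posed with the tuning-curve code and taste-balanced rating
  means (valence varying only trial to trial), where taste is
  genuinely uninformative — and there the ANOVA attributes the signal
  to valence alone.  Conversely, a planted taste-only code with
  confounded ratings yields a taste effect with valence and
  interaction at their nominal false-positive rates.
* The similarity analysis needs a stronger planted amplitude than the
  searchlight does: Pearson correlation has no whitening step, so the
  0.08 amplitude that puts sphere decoding at 75% leaves the
  correlation contrast underpowered at 20 subjects.  The
  disentanglement analyses therefore run at `taste_amp = 0.2`
  (median taste F ≈ 50 across replicate cohorts, the order of
  magnitude a 20-subject within-subject design reports), while
  recovery and inference analyses run at the decoding-calibrated
  default.

## Problem sizes and numerical choices

The shipped analyses and tests run on a 20×24×18 grid at 2 mm (a
down-sampled field of view holding a ~330-voxel mask and an 80-voxel
core), 12-subject cohorts for the workflow scripts, 2000-realisation
nulls for the single-subject threshold, 500–2000 sign flips for group
nulls, and 100-replicate power runs for the ANOVA criteria; the full
40×48×36 grid works unchanged.  Everything stochastic is seeded:
subjects by `seed`, the planted anatomy by `pattern_seed` (kept
separate so a cohort shares one ground truth), permutations by their
own `seed` arguments, with fold seeds derived additively.  Quantiles
use R's type-7 definition except the FWE threshold, which uses the
inverse-ECDF (type-1) quantile of the max-t null so that "t exceeds
the threshold" matches "corrected p below alpha".  Fisher z-transforms
clip |r| at 1 − 1e−12 to keep degenerate perfect correlations finite.

## What passing these tests does and does not show

The generator emulates the statistical skeleton the analyses assume —
balanced designs, smooth stationary Gaussian noise, stable planted
codes, honest trial-by-trial rating variability — and none of the
physiological structure of real data: no motion, no cardiac or
respiratory cycles, no scanner drift beyond a linear term, no
between-subject anatomical variability (all subjects share one mask
and one planted code), and hemodynamics exactly matching the analysis
HRF.  Green tests therefore certify the *machinery* — recovery where
recovery is possible, chance-level behaviour and controlled error
rates under the null, agreement with independent oracles — not the
neuroscience of any particular dataset.
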