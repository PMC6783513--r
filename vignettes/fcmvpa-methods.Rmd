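---
title: "Connectivity-based MVPA for resting-state fMRI: models and design"
author: "fcmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based MVPA for resting-state fMRI: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`fcmvpa` implements a complete resting-state fMRI functional-connectivity
analysis of the kind used to search for single-subject neuromarkers of
clinical conditions such as primary insomnia: temporal preprocessing of BOLD
series, three per-subject connectivity feature types (voxel-wise functional
connectivity strength, atlas-based large-scale FC, regional homogeneity),
cross-validated linear-SVM classification with permutation significance,
discriminative weight mapping, and mass-univariate group statistics with
Monte-Carlo cluster-extent correction. Because clinical rs-fMRI cohorts are
rarely shareable, the package also ships a synthetic cohort generator with a
known, recoverable group effect; every downstream stage is tested against it.

# Temporal preprocessing

The chain is `discardInitial` (default 10 volumes, signal equilibration)
`->` `detrendLinear` `->` `bandpassFilter` (0.01–0.1 Hz) `->`
`regressNuisance` (Friston-24 motion expansion + CSF + white matter + global
mean; 27 columns when all are enabled).

*Filter implementation.* The band-pass is the ideal discrete-Fourier boxcar:
frequency bins strictly outside the band, and always the zero-frequency bin,
are zeroed. It is implemented as a projection onto the orthonormal basis of
retained real Fourier modes (two matrix products), which is algebraically
identical to FFT-zero-inverse (verified to 3e-14 in development) and far
faster for many short columns in R. A boxcar zeroes *bins*; an out-of-band
tone that is not bin-aligned leaves a small leakage residual, which is
inherent to DFT filtering and not an artifact of this implementation.

*Regression design.* `regressNuisance` always augments the design with an
intercept and a linear ramp, and by default band-filters all non-intercept
regressors with the same band as the data. Two consequences:

1. The regression cannot reintroduce frequencies outside the pass band.
2. The full chain is an *exact* fixed point on already-processed data
   (machine precision), because every design column then lies in the band
   space: a second pass finds nothing left to remove. The test suite asserts
   this at 1e-9.

Regressors whose in-band content vanishes after filtering (e.g. squares of
very slow motion drifts) are dropped with a message; a genuinely
rank-deficient design is an error naming the collinear columns. One hard
constraint follows: the number of retained Fourier modes must exceed the
design size. At TR 2.5 s and 0.01–0.1 Hz, a series of `T` retained volumes
offers about `0.09 * 2.5 * 2 * T` modes, so the full 29-column design needs
roughly `T >= 130`; the defaults (240 volumes, 10 discarded) give 82 modes.

Whether nuisance regressors should themselves be filtered is not settled
practice; filtering them is the default here (switchable via `band = NULL`)
because it keeps the projection interpretation exact.

# Feature types

**FCS** (functional connectivity strength): for every gray-matter voxel, the
sum of its Pearson correlations with all other gray-matter voxels that
exceed `r = 0.25` (weak and negative correlations removed; the
self-correlation excluded). The computation is chunked so the full
voxel-by-voxel correlation matrix is never held at once; a brute-force
O(V^2) double loop serves as the oracle in tests, with exact agreement
required. "Conversion to z scores" of a *sum* of correlations is ambiguous
(the sum exceeds 1, so `arctanh` of the sum is not meaningful); both
readings are provided — in-mask map standardization (`zscoreMap`, default)
and `arctanh` applied to each suprathreshold correlation before summation
(`fcsScaling = "fisher"`) — and neither is asserted to be the published
intent. The gray-matter mask uses a strict inequality (probability
`> 0.2`), pinned by a test. The FCS threshold is likewise strict (`> 0.25`).

**Large-scale FC**: node-mean time series over an integer-labeled
parcellation, Pearson correlations of all unordered node pairs, Fisher
z-transform, packed in row-major strict-upper-triangle order with an
explicit pair index map. A 268-node atlas gives 268*267/2 = 35,778 features.
Correlations of exactly |r| = 1 (possible with duplicated synthetic series)
are clamped to 1 - 1e-7 with a warning before `arctanh`.

**ReHo** (regional homogeneity): Kendall's coefficient of concordance W of
each voxel's series with its in-mask 26-neighborhood (27 series including
the center; 19 and 7 also supported), computed from midranks with no
tie-correction term. Edge voxels use the neighbors available; a voxel with
no in-mask neighbor is set to 0 and flagged. Maps are normalized by the
in-mask mean (so the normalized map averages exactly 1) and then smoothed.

**Smoothing**: separable Gaussian, `sigma = FWHM / (sqrt(8 ln 2) * voxel)`,
applied on the zero-filled grid and re-masked. By default the result is
divided by the smoothed mask ("mask renormalization") so that a constant
in-mask image is unchanged; synthetic masks have a high surface-to-volume
ratio and would otherwise suffer strong edge attenuation.

Feature flattening uses the volume's native column-major linear order as the
pinned scan order, stored in each `FeatureTable`'s index map so weight
back-projection is unambiguous and round-trips exactly.

# Classification

Stratified 5-fold cross-validation ("8 to 2" per class): within each class,
subjects are shuffled by seed and dealt into k near-equal test blocks
(sizes differ by at most 1 — for 38/44 subjects the test blocks are
8,8,8,7,7 and 9,9,9,9,8). Per fold: feature standardization with train
mean/sd (sample sd; zero-variance features zeroed and recorded), PCA fit on
the training rows *retaining all components*, a linear soft-margin SVM
(`e1071`, cost 1 by default — the cost, library and scaling variant are not
pinned by published practice, so the cost is exposed in `cvConfig`), and the
identical transform chain applied to the test rows. Retaining all components
makes the PCA a pure rotation; the package treats the resulting invariance
as its key correctness oracle, asserting that decision values with and
without the PCA stage agree to 1e-6.

Weights are back-rotated into standardized-feature space (`w = R w_pc`) and
reported there, since that is the space the classifier saw; they are
averaged over folds, and each fold's orientation is fixed so positive
weights point toward the patient class. Sensitivity counts patients
(positive class), specificity controls; AUC is computed per fold from the
decision values by the Mann–Whitney rank identity and averaged over folds
(a fold with a single-class test block yields a missing AUC, excluded from
the mean with a warning). Pooled per-subject predictions form one 2x2
confusion matrix whose entries sum to the cohort size.

The permutation test applies one global label permutation per iteration and
reruns the *entire* cross-validation, so every training set inherits
permuted labels; `p = (N_exceed + 1) / (N_permutation + 1)`, with ties
counting as exceedances. At 1000 permutations the attainable floor is
1/1001 < 0.001. One calibration subtlety: at small n the accuracy metric
lives on a coarse grid, so ties with the observed value are common and the
ties-count-as-exceed convention makes its permutation p conservative
(stochastically larger than uniform). The AUC metric is effectively
tie-free, and the null-uniformity property is asserted on it; the
conservative direction for tied metrics never inflates false positives.

`residualizeConfound` removes a covariate (e.g. PSQI) from every feature by
full-sample linear regression, replicating the published procedure; this
leaks the covariate distribution across folds, which is documented, and a
leakage-free per-fold variant (train-fit slopes) is available through
`cvConfig(residualizeWithin = )`. `filterSeverity` implements the stricter
patient inclusion rule (duration > 6 months, total sleep time <= 390 min,
and SOL > 45 or WASO > 45 or SOL + WASO > 60 min).

# Weight maps and clusters

`vectorToMap` inverts the feature flattening. `topPercentThreshold` keeps
the `ceiling(pct/100 * V)` in-mask voxels of largest *absolute* value (the
published weight tables contain both signs); ties at the cutoff are all
retained and logged. Connected components use 26-connectivity by default
(6/18 available) with positive and negative voxels labeled separately, so
opposite-signed clusters cannot merge through adjacency and the peak weight
of a cluster is sign-unambiguous. Peaks are reported in world mm via the
NIfTI affine (0-based voxel convention; R-side 1-based indices are converted
internally).

# Group statistics

`voxelwiseGLM` fits per-voxel OLS on `[intercept, group, age, sex,
education]` and returns the t statistic of the group contrast
(patient - control) with `df = n - p`; residual maps are retained.
Two-sided thresholds are used throughout, since both increases and
decreases are of interest.

Residual smoothness is estimated by the classical Gaussian-field
first-differences formula (no method is pinned by published practice, so
the AFNI-style estimator was chosen): per axis,
`FWHM = voxel * sqrt(-2 ln 2 / ln(rho))` with `rho = 1 - s2_diff/(2 s2)`
the lag-1 in-mask neighbor correlation, averaged over subjects;
subject-axis combinations with non-positive `rho` are flagged and skipped.
The estimator recovers an 8 mm kernel within 15% on 24^3 grids (asserted
over 50 replicates).

The AlphaSim-style correction simulates Gaussian white noise on the full
grid, smooths it to the estimated per-axis FWHM, and divides by the *known*
per-voxel standard deviation of smoothed unit noise (computable exactly via
the squared separable kernels), so the voxel-level threshold
`|z| > z(1 - p/2)` is exact under the null even near mask edges. The
largest suprathreshold component within the mask (sign-split, same
connectivity as cluster extraction) is recorded per iteration; the minimum
significant size is the smallest k with empirical
`P(max cluster >= k) <= alpha`. Applying the correction to a t map uses the
t quantile at the same voxel p; simulating Gaussian fields for t statistics
is the standard AlphaSim approximation and is slightly liberal at very low
df. The family-wise error of the full pipeline (GLM -> smoothness ->
AlphaSim -> correction) is asserted to sit inside the binomial 95% band
around 0.05 on 200 null cohorts.

Edgewise (large-scale FC) tests use Benjamini–Hochberg FDR via
`p.adjust(method = "BH")`, cross-checked against an independently coded
step-up oracle. Cluster–score correlations average each subject's map over
the cluster voxels and report Pearson r with its two-sided t-transform p;
the published analysis restricts to patients, which is the default subset.

# The synthetic cohort generator

The generator emulates a two-group rs-fMRI cohort already in a common space:
gray matter is a set of disjoint cuboid regions on a 24^3 grid of 3 mm
voxels (64 regions of 3^3 voxels by default, laid on a lattice with
1-voxel gaps so regions stay disconnected even under 26-connectivity); each
region carries a unit-variance stationary AR(1) latent (`ar1Coef = 0.4`)
and each voxel observes its region latent plus white noise
(`noiseSd = 0.45`). Acquisition parameters follow the targeted protocol:
240 volumes at TR 2.5 s. The gray-matter probability map is 0.9 inside
regions and 0.05 outside, so thresholding at 0.2 recovers the region union
exactly.

**The injected effect** is hub-like: in patients, the effect region mixes in
the average of P = 3 partner latents (`sqrt(c) * gbar`) while each partner
mixes in its own (`sqrt(c) * g_p`), giving latent correlations
`corr(effect, partner) = c / sqrt(3)` with partners mutually uncoupled, so
the effect region's FCS gain is about three times a partner's and the
discriminative map has a single dominant region. The subject-level realized
coupling `c` is `effectStrength` jittered by ±15%. Clinical scores (ISI,
PSQI, SAS, SDS) are `group intercept + slope * c + noise`, with intercepts
and spreads matching typical published insomnia/control questionnaire
means, so score–connectivity correlations have a recoverable ground truth
tied to each subject's realized coupling rather than the bare group label.

Three generator constants were calibrated while designing the recipe, not
against any test outcome dial-turning afterwards: `noiseSd = 0.45` and
`couplingJitter = 0.15` keep the worst-case effect–partner voxel
correlation (~0.31) above the fixed FCS threshold of 0.25 (with the first
draft values the injected effect straddled the threshold and was silently
erased); and 64 regions balance two scale-coupled requirements — the top-1%
weight count (`ceiling(0.01 * 1728) = 18` voxels) must be commensurate with
the 27-voxel effect region for overlap scores to be attainable, while too
many regions dilute classifier accuracy because global-signal regression
(part of the published pipeline) redistributes a small, consistent
anti-correlated signal over every region.

What the generator does *not* emulate: hemodynamic response shapes,
physiological (cardiac/respiratory) noise, susceptibility artifacts,
inter-subject anatomical variability, realistic motion artifacts (motion
parameters are small smooth random walks that exercise the Friston-24
plumbing but carry no injected artifact), or realistic gray-matter
topology. Passing tests therefore demonstrate the *machinery* — exact
oracles, leakage-free cross-validation, calibrated error control, and
recovery of a planted effect — not performance on real brains.

CSF and white matter have no synthetic anatomy; the last two regions act as
proxy compartments for the tissue regressors, and the global signal is the
whole gray-mask mean. With `effectStrength = 0` the two groups are drawn
from the identical generative law (the coupling draw is consumed either
way, keeping RNG streams aligned), which the exchangeability tests exploit.

# Numerical choices and degenerate inputs

- Fisher transform at |r| >= 1: clamp to 1 - 1e-7 and warn.
- Zero-variance series in FCS: error listing the voxel indices.
- Zero-variance features in CV standardization: column zeroed, recorded.
- Kendall's W with constant series: computed with midranks, flagged.
- ReHo voxel with no in-mask neighbor: set to 0, flagged.
- Ties at the top-percent cutoff: all retained, logged.
- Map standardization uses the population sd (pinned by a worked example).
- Smoothing kernels truncate at 4 sigma (clamped to the grid).
- `minSize` search in the cluster correction walks k upward, so
  `clusterAlpha = 1` returns 1 and an all-large null returns max + 1.

# Problem sizes in the test suite

The calibration suites run at sizes chosen for a single CPU: a shared pool
of 200 preprocessed null cohorts (n = 10+10, 24^3 grid, 12 regions) serves
the chance-level accuracy check (100 cohorts, large-scale FC features), the
permutation-uniformity check (200 repeats at 99 permutations), and the
family-wise-error check (200 replicates at 200 Monte-Carlo iterations,
unsmoothed ReHo maps — at this block geometry a 6 mm kernel exceeds the
blocks' internal degrees of freedom, which would make apparent smoothness,
and hence the cluster-extent threshold, degenerate). Signal-recovery runs
use the full default geometry at n = 20+20 and effect strength 0.8 over 10
seeds. The whole suite completes in roughly a quarter hour.

# Known limitations

- The AlphaSim Gaussian-field approximation to t fields is slightly liberal
  at low df (a property of the method, shared with common toolboxes).
- DFT band-pass filtering assumes the retained window is representative;
  no tapering is applied, matching common rs-fMRI toolbox behavior.
- Full-sample confound residualization replicates published practice and
  leaks across CV folds; prefer `residualizeWithin` for new analyses.
- The synthetic block world cannot say anything about anatomical
  localization quality on real data; world-coordinate reporting is exact
  but the coordinates are only meaningful relative to the synthetic grid.
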