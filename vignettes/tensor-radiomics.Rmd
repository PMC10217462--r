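---
title: "Tensor radiomics for PET/CT outcome prediction: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor radiomics for PET/CT outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

`tensorRad` implements a multi-flavour ("tensor") radiomics pipeline for
binary outcome prediction from co-registered PET/CT volumes with a tumor
mask. The core idea is to not choose a single input image: each patient's
CT and PET are combined by 15 image-level fusion techniques, and every
feature is extracted once per *flavour* (CT, PET and the 15 fusions),
giving a patients x features x flavours tensor. The learning stage then
combines flavours rather than discarding them:

* **tensor handcrafted-feature (RF) chain** - median imputation, greedy
  correlation filter (threshold grid-searched over {0.8, 0.95} on inner
  validation, candidates ordered by the one-way ANOVA F statistic),
  degree-2 polynomial flavour fusion (per base feature: each
  surviving flavour, its square and all pairwise cross-flavour products -
  never cross-feature terms), ANOVA top-k selection, z-scoring, and three
  classifier families (MLP, random forest, L2-regularized logistic
  regression);
* **tensor deep-feature (DF) chain** - variance filter, PCA flavour fusion
  (centering and loadings fit on training rows only), ANOVA top-k,
  z-scoring and the same classifiers;
* **conventional chains** - the same machinery applied to a single named
  flavour, for comparison;
* **end-to-end 3D CNN** - the encoder stack followed by global average
  pooling and a sigmoid unit, trained directly on one flavour's volumes.

Evaluation is 5-fold nested cross-validation: four folds train, and of
those training patients 80% fit every stage of the chain, 20% validate
model selection; the held-out fold is touched only by final ensemble
prediction. The ensemble has nine members - the top three
inner-validation configurations from each classifier family - and votes
by majority, ties broken by mean predicted probability, then class 0.
Every fitted transform records the row set it was fit on, so leakage can
be audited mechanically from the returned report.

## Handcrafted features

`extractFeatures()` returns 215 features in a fixed, documented order
(`featureNames()`, also shipped as `inst/extdata/feature_names.csv`): 79
first-order (29 morphology, 2 local-intensity peaks, 18 intensity
statistics, 23 intensity-histogram, 7 intensity-volume-histogram) and 136
3D texture features (GLCM 25 and GLRLM 16, each under both the averaged
and merged 13-direction aggregations; GLSZM and GLDZM 16 each; NGTDM 5;
NGLDM 17), following the IBSI definitions. Zones and dependence counts
use 26-connectivity; the distance-zone map uses the Chebyshev distance to
the mask edge. Grey levels come from fixed-bin-number discretization
(default `ng = 32`, within-mask min/max); FBN keeps flavours with very
different dynamic ranges comparable, and `ng` is configurable because
published binning settings vary.

Morphology uses a surface mesh obtained by marching tetrahedra on the 0.5
level set of the mask after one pass of separable [1,2,1]/4 smoothing,
with linearly interpolated edge crossings. Meshing the raw binary
staircase instead overestimates surface area by roughly 30% on digital
spheres (sphericity ~0.77 for a radius-8 ball); the smoothed-field mesh
recovers sphericity within ~1% and volume within ~2% at that radius,
which is what the sphere oracle in the test suite checks. The maximum 3D
diameter is the largest pairwise distance between convex-hull vertices of
the mesh (hull computed by an incremental algorithm); the
minimum-volume-enclosing ellipsoid uses Khachiyan's algorithm on the hull
vertices (tolerance 1e-3); the oriented bounding box is the PCA-aligned
box, a standard approximation to the true minimal box. Moran's I and
Geary's C subsample at most 600 in-mask voxels (deterministic, evenly
spaced) to bound the O(n^2) pair sums.

Undefined values (zero-variance moments, single-level co-occurrence
correlation, NGTDM coarseness with a zero denominator, mesh features of a
single-voxel mask) are emitted as `NA` and imputed downstream by
training-fold medians inside cross-validation - never silently zeroed
and never imputed globally.

## Fusion constructions

The registry (Laplacian pyramid LP, ratio-of-low-pass pyramid RP,
separable wavelets DWT/db4 and WAVELET/sym4, dual-tree complex wavelet
DTCWT, curvelet-style CVT, contourlet-style NSCT, sparse representation
SR, three SR hybrids, cross-bilateral BCF, WEIGHTED w = 0.5, PCA, HSI) is
closed and each construction sits behind one registry entry so variants
can be swapped. Choices that were genuinely open:

* Transforms run 2D on axial slices and are restacked - the common
  practice in fusion toolboxes; 3D transforms are out of scope.
* DTCWT is built from two orthogonal trees (db4 and its time reverse)
  separably in 2D; per-coefficient fusion selects jointly across the four
  sub-trees by the quadrature modulus, which keeps the selection
  approximately shift-invariant while each tree reconstructs exactly.
* CVT and NSCT are FFT-domain nonsubsampled decompositions: smooth radial
  windows that telescope to one (3 scales) times angular windows that
  partition [0, pi) (CVT: 8/8/8 triangular; NSCT: 8/8/4 raised-cosine).
  Reconstruction is the plain band sum, exact to FFT round-off, well
  inside the 1e-3 tolerance the tests allow these two constructions.
* Coefficient rules: low-pass mean; detail max-absolute (RP: ratio
  farthest from 1); ties keep the CT coefficient, which makes the
  symmetric-rule methods order-stable.
* SR: a K-SVD dictionary (unit-norm atoms, OMP coding, approximate
  rank-1 atom updates; training stops rather than accept an error
  increase, so the recorded error trace is non-increasing) is trained per
  patient on mean-removed 8x8 patches pooled from both modalities. Patch
  selection keeps the source whose sparse code has the larger L1 norm (an
  all-zero code is never selected); the selected source's patch content
  is written back and overlaps are averaged. Writing back the original
  patch rather than its OMP approximation makes SR fusion exactly
  idempotent on identical inputs, which the package treats as
  non-negotiable; the sparse codes serve as the activity measure. Hybrids
  apply SR to the low-pass band and max-abs to details.
* Fused volumes are clamped (not re-scaled) to [0,1], so fusing an image
  with itself returns it unchanged.
* HSI: intensity is the modality mean, saturation the CT-PET difference,
  hue taken from PET on a 300-degree wheel, then back-converted to
  luminance. Where the modalities agree the output equals the input,
  which keeps the idempotence property that all methods share.

## Deep features and the CNN baseline

The 3D autoencoder is three conv(3x3x3) + LeakyReLU(0.1) + 2x maxpool
encoder stages and a mirrored upsample/conv decoder with a final sigmoid,
trained with Adam on mean binary cross-entropy (inputs must lie in
[0,1]). The flattened activations after the third pooling stage are the
deep-feature vector; on the 224 x 224 x 160 reference grid (in-plane 1 mm,
through-plane 1.4 mm, 224 mm physical box) with one bottleneck channel
this is 28 * 28 * 20 = 15,680 units. Channel widths default to 16 -> 8 ->
bottleneck. All layers (forward and backward) are implemented in C++;
seeds fix initialization and batch order, so loss traces are bit
reproducible on one machine.

One autoencoder is trained per flavour per outer fold, on (a subsample
of) that fold's inner-training patients only - deep features never see
validation or test patients before extraction. Desk-scale runs use
32-voxel grids with a narrow autoencoder (widths 2/2, 2 bottleneck
channels, 2 epochs, at most 12 training volumes per fold); the reference
configuration is exercised by a single forward pass in the acceptance
suite, not trained.

The CNN baseline reuses the encoder topology plus global average pooling
and a dense sigmoid output, so the end-to-end comparison isolates how the
same capacity is used. Its nine ensemble members are three random
restarts crossed with three epoch checkpoints.

## The phantom generator

`generateCohort()` draws, per patient, two latent variables in [0,1]: a
CT morphology latent m and a PET texture latent t. The tumor mask is a
star-convex blob - a sphere whose boundary radius is modulated by random
degree-2/3 spherical harmonics with relative amplitude m times the
`irregularity` ceiling (0.35), normalized so m = 0 is an exact sphere and
the stated amplitude is the maximum modulation. CT shows the tumor as a
homogeneous dense region over a smooth background field, so CT carries
shape information only; PET uptake inside the tumor is textured by a
Gaussian random field whose correlation length interpolates 1-4 voxels
with t, so PET carries texture information only. Labels are *sampled*
from Bernoulli(plogis(b0 + bm(2m-1) + bt(2t-1))) (defaults b = 0, 2, 2),
not thresholded, keeping the Bayes accuracy well below 1 so overfitting
is detectable. Defaults: 48-voxel grids at 2 mm spacing, tumor radii
8-14 mm, additive Gaussian noise (sd 0.03 CT / 0.05 PET). The random
field itself is spectral synthesis with Gaussian autocorrelation
(rho(l) = exp(-1/2) at one correlation length), standardized to unit
variance.

What the phantoms do *not* emulate: anatomy, scanner physics (PSF,
Poisson sinogram noise), SUV calibration, registration error, or
segmentation variability. Passing tests therefore demonstrate that the
pipeline recovers the planted two-modality structure under controlled
conditions - not clinical performance.

## Problem sizes used by the tests and the acceptance script

All sizes below are the package's own desk-scale choices, made once:

* texture-matrix oracle equivalence: 100+ random volumes up to 5x5x5 per
  family against exhaustive brute-force enumeration;
* pipeline-integrity checks (leakage audit, permuted-label chance): 60
  phantoms on 16-voxel grids at 3 mm spacing, 20 permutation seeds per
  framework; deep features for the permutation null come from a fixed
  (label-independent) autoencoder so that only the label-dependent
  stages re-run per permutation, while the leakage audit runs on the
  full per-fold path;
* parameter recovery (tensor vs. best sole modality, accuracy target
  0.65): 100 phantoms on 32-voxel grids at 2 mm spacing, averaged over 2
  seeds, with the reduced autoencoder and a reduced sparse-representation
  profile (48 atoms, 2 K-SVD iterations, 800 training patches);
* the reference 224 x 224 x 160 autoencoder is verified by one forward
  pass (bottleneck length 15,680), never trained at that size.

## Numerical choices and degenerate inputs

* Trilinear resampling fills points outside the source volume with the
  source minimum (air for CT, zero uptake for normalized PET); the same
  value pads the fixed-size crop. Masks always resample nearest.
* A constant volume min-max normalizes to all zeros; histogram
  equalization leaves constant slices untouched.
* FBN discretization of a constant region assigns level 1 everywhere.
* The greedy correlation filter considers at most `max_corr_candidates`
  (default 1200) columns in decreasing F order before the O(n k p) pass;
  on the full 3655-column handcrafted tensor this bounds the cost while
  keeping every plausibly selectable column (selection later keeps only
  the top 8-50).
* PCA components are capped at the training-row rank; requesting more is
  an error, not a silent truncation.
* Ensemble ties (possible only with an even effective member count) fall
  back to the mean probability, then class 0 - deterministic by
  construction.
* All randomness descends from one user-visible seed per entry point;
  internal helpers save and restore the global RNG state.

Permutation nulls are judged against the no-information rate (the
majority-class prevalence of the cohort draw), not against 0.5: under
permuted labels a degenerate majority predictor legitimately scores the
prevalence, and the meaningful property is that no framework performs
*better* than that.

## Known limitations

* The OMBB and MVEE morphology densities are approximations (PCA-aligned
  box; Khachiyan at 1e-3) - adequate for ranking patients, not for
  sub-percent geometry work.
* 2D slice-wise fusion ignores through-plane structure.
* The correlation filter's candidate cap and the desk-scale autoencoder
  are pragmatic bounds; both are configuration, not architecture.
* Accuracies on the synthetic cohorts characterize the pipeline under
  the generator's assumptions only; no claim transfers to clinical data
  without the corresponding cohort.
* On these phantoms the tensor pipelines do not reliably beat the best
  sole-modality pipeline at desk scale, and the recovery tests record
  that as a failure rather than hiding it. Two structural reasons: the
  morphology feature block is computed from the tumor mask, which every
  flavour shares, so even a sole-PET model sees the shape signal; and
  selecting from the ~3,600-36,000-column tensor pools at 60-80
  training patients pays a selection-noise penalty that a 215-column
  single-flavour model does not. The deep tensor chain is additionally
  capped by the desk-scale autoencoder (a 128-unit bottleneck stands in
  for the 15,680-unit reference). Larger cohorts and the full-size
  autoencoder are the configuration under which the cross-flavour
  ordering would be expected to emerge.
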