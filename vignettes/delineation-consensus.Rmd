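---
title: "Consensus contours, observer variability and SUV thresholds: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus contours, observer variability and SUV thresholds: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stapleseg)
```

This vignette is the package's own account of the models it fits, the
parameters that matter, the numerical choices behind them, and what the
synthetic data can and cannot tell you about real contouring studies.

## 1. The STAPLE model

All delineations live on one voxel grid (`image_grid`): shape, spacing in
mm, origin, and an orthonormal direction matrix, i.e. the standard NIfTI
affine with 0-based indices. The package refuses mixed grids
(`assert_same_grid()`, tolerance 10^-3 mm) instead of resampling, because
silent resampling would quietly corrupt every overlap metric downstream;
co-registration is assumed to have happened upstream in the planning
system.

`staple()` treats the true segmentation as a latent binary field $T_i$ and
observer $j$'s decision $D_{ij}$ as a noisy channel with sensitivity
$p_j = P(D_{ij}=1 \mid T_i=1)$ and specificity
$q_j = P(D_{ij}=0 \mid T_i=0)$, independent across voxels and observers.
With a global foreground prior $\gamma$, EM alternates

$$a_i = \gamma \prod_j p_j^{D_{ij}}(1-p_j)^{1-D_{ij}},\qquad
  b_i = (1-\gamma) \prod_j (1-q_j)^{D_{ij}} q_j^{1-D_{ij}},\qquad
  W_i = \frac{a_i}{a_i+b_i},$$

$$p_j \leftarrow \frac{\sum_i W_i D_{ij}}{\sum_i W_i},\qquad
  q_j \leftarrow \frac{\sum_i (1-W_i)(1-D_{ij})}{\sum_i (1-W_i)}.$$

This is the spatially unregularized binary form; Markov-random-field
variants with spatial homogeneity constraints are deliberately out of
scope, as is multi-label or probability-map-input fusion.

Choices a user can change, with defaults and reasons:

* **Initialisation** `init_sensitivity = init_specificity = 0.9`. Standard
  practice; starting at 1.0 would be an absorbing state.
* **Prior** `prior = "mean_occupancy"`: $\gamma$ is the mean observer
  occupancy fraction on the analysis region and is *not* updated by EM
  (a fixed user value is the alternative). Updating $\gamma$ is a
  non-goal; with it fixed, the observed-data log-likelihood
  $\sum_i \log(a_i+b_i)$ is still non-decreasing, which the fit records in
  `trace$loglik` and the tests assert on every run.
* **Analysis region** `bbox_margin = 5` voxels around the bounding box of
  the union of masks. A PET field of view is overwhelmingly background; if
  the whole grid entered the sums, $\gamma$ would be driven towards zero
  and every specificity towards one, regardless of the contours. Voxels
  outside the region are unanimous background: they carry posterior weight
  0 and are excluded from the E/M sums. Consequently $q_j$ is
  interpretable *within the region*; enlarging the margin nudges $q_j$
  toward 1 but leaves the consensus mask unchanged, which is tested
  (margin 5 vs 10).
* **Convergence** relative change of $\sum_i W_i$ below `tol = 1e-6`, at
  most `max_iter = 100` iterations. Cheap and sufficient at lesion scale
  (typically 10–20 iterations).
* **Consensus cutoff** `consensus_mask(fit, cutoff = 0.5)`, with ties at
  the cutoff *included* so the rule is deterministic.

Numerical details: the E-step runs in log space with probabilities clamped
to $[10^{-12}, 1-10^{-12}]$, so unanimous raters converge to $p_j = q_j = 1$
without `log(0)`; a collapse of either posterior mass sum raises an error
naming it. Two perfectly disagreeing raters (a mask and its complement) are
degenerate but defined: the weights equal the prior everywhere and the fit
converges — documented behaviour, not an error.

## 2. Agreement metrics

`dice()` is $2|A\cap B|/(|A|+|B|)$ (undefined and an error for two empty
masks). `mask_volume()` is the occupied count times the voxel volume.
`hausdorff()` is the classical symmetric maximum over nearest-boundary
distances: boundaries are occupied voxels with a face-adjacent
(6-neighbourhood) background or out-of-bounds neighbour, and distances are
Euclidean between voxel centres in mm. The implementation samples a
separable (Felzenszwalb) squared Euclidean distance transform — computed in
C++ on the joint bounding subgrid with anisotropic spacing — at the other
boundary's voxels; the test suite pins it against an all-pairs
boundary-distance scan written independently in R.

Assumptions worth knowing: the distance is voxel-centre based (no sub-voxel
surface meshes), and the default is the 100th-percentile (true maximum)
form, which is the variant consistent with reporting large outlier
distances from single faulty delineations; a `percentile` argument exposes
the robust 95 % variant. Average surface distance and similar metrics are
out of scope.

## 3. SUVmax-percentage thresholding

`threshold_segment(pet, roi, t)` finds SUVmax within the ROI (ties broken
to the lexicographically smallest index), forms
$S = \{\,\mathrm{SUV} \ge (t/100)\cdot \mathrm{SUVmax}\,\}$ with $\ge$ at
the cutoff (so $t = 100$ retains the maximum voxel), and keeps the
connected component of $S$ containing the SUVmax voxel. Defaults:

* **Connectivity 26** (6 available): the more inclusive convention for
  PET component growth.
* **Unclipped growth** (`clip_to_roi = FALSE`): the component may escape
  the ROI. This reproduces a real failure mode — with a nearby
  physiological hot spot (the pituitary gland under somatostatin-receptor
  tracers) a suprathreshold bridge lets the segmentation leak into it.
  `clip_to_roi = TRUE` is the guard.
* **Default ROI** (`default_roi()`): padded bounding box (3 voxels) of the
  union of available masks, an operational stand-in for "within the
  lesion" that needs no manual input.

Internally both the single cut and the sweep derive from one bottleneck
(max–min path) flood from the seed, computed in C++ with a priority queue:
a voxel's capacity is the highest threshold at which it is still connected
to the seed. Thresholding the capacity field reproduces the seeded
component exactly (pinned against a breadth-first flood-fill oracle in the
tests) and makes the sweep over 201 thresholds a sort rather than 201
region growths; nesting of segmentations in $t$ holds by construction and
is still asserted.

`sweep_thresholds()` scans $t = 0, 0.5, \dots, 100$ and selects the $t$
maximizing the unweighted mean Dice against the per-lesion consensus
references, ties breaking toward the *smaller* threshold — the more
inclusive GTV, the conservative radiotherapy choice (a documented
package decision, not a claim about how others break ties). Lesions whose
segmentation is empty would score Dice 0 rather than dropping out of the
mean. `evaluate_on_validation()` applies one fixed threshold with no
re-optimization; an empty segmentation there scores Dice 0 and an
undefined (`NA`) Hausdorff distance.

## 4. The study pipeline and its statistics

`compute_iov()` builds one consensus per (lesion, condition) from that
condition's observers only and scores each observer against their own
condition's consensus. `compare_modalities()` pairs records on
(lesion × observer) — multiple lesions of one patient are treated as
independent, a deliberate simplification that mirrors how such lesions are
analysed when their delineations do not interact, and a caveat for real
data with patient-level clustering. The paired Wilcoxon signed-rank test
drops zero differences (Wilcoxon's original treatment), uses the exact
null up to 25 non-zero pairs and the normal approximation with continuity
correction above; the exact branch is pinned against full $2^n$ sign
enumeration in the tests, and the approximation's size at study scale
(135 pairs) is checked empirically against its nominal 5 % level.
`correlate_threshold_volume()` reports Spearman's rho computed as Pearson
on average ranks, with the two-sided p from `stats::cor.test`. No
multiplicity correction is applied across the three metric comparisons —
raw p-values are reported. All tests are two-sided at $\alpha = 0.05$.

`run_study()` orchestrates everything from a config list or YAML file
(synthetic spec or CSV tables of NIfTI paths), writes tidy CSV/JSON
outputs plus a manifest with the seed and versions, and is byte-for-byte
reproducible under a fixed seed. Without PET volumes it runs the
single-condition IOV half and announces that the sweep is skipped.

## 5. What the synthetic data emulates — and what it does not

`make_phantom()` builds an ellipsoidal truth (voxel centres inside the
ellipsoid) and a PET volume: piecewise-constant uptake convolved with an
isotropic Gaussian point-spread function, plus additive Gaussian noise
clipped at zero. Defaults, chosen once for the whole package:

| parameter | default | rationale |
|---|---|---|
| grid | 64×64×32 @ 4×4×5 mm | brain-PET matrix voxel size, test-fast |
| lesion uptake | SUV 8 (studies draw 5–12) | high somatostatin-receptor tracer uptake |
| background | SUV 0.2 | near-negligible physiological brain uptake |
| PSF FWHM | 6 mm | reconstructed PET resolution scale |
| noise sd | SUV 0.2 | visible but not dominant image noise |
| semi-axes | ~(16, 14, 12) mm (studies draw 8–18) | cm³-scale lesions |

Noise is Gaussian in image space, not Poisson in projection space:
reconstruction simulation is out of scope and only image-domain statistics
reach the pipeline. The blur kernel rows are renormalized at the grid
edge so flat fields stay flat. A `decoy` hot spot (centre, radius, uptake)
emulates the pituitary confounder and must not overlap the lesion unless
explicitly allowed.

`simulate_observers()` has two error modes. `iid_flip` flips each voxel
independently with the observer's $(p_j, q_j)$ — *exactly* the generative
model STAPLE assumes, which makes rater-parameter recovery a well-posed
check. `boundary_field` thresholds the signed distance to the truth
surface at $b_j + \varepsilon_j(x)$, where $b_j$ is a constant
per-observer bias and $\varepsilon_j$ a smooth zero-mean Gaussian field
(white noise filtered at 10 mm correlation length, then standardized) —
contiguous over- and under-contoured regions rather than salt-and-pepper
disagreement, closer to how experience levels shift real contours.

`make_study()` assembles the default study: 27 lesions, 5 observers, two
conditions, with boundary noise sd 2.5 mm and biases ±1.2 mm in the
MRI-only condition versus 1.5 mm and ±0.6 mm with PET — the planted
"PET reduces IOV" effect. The validation group defaults to 12 lesions and
3 observers in the PET condition only. These problem sizes are the
package's chosen simulation scale: large enough for the paired tests to
resolve the planted effect, small enough that a full study simulates and
analyses in seconds.

What passing tests on these phantoms *does not* show: realism of MRI
appearance, reconstruction artefacts, anatomically shaped lesions (falx,
skull-base infiltration), patient-level clustering of lesions, or
systematic inter-modality registration error. Results on synthetic studies
demonstrate that the estimators and the pipeline are correct and
well-calibrated under their stated models — not that any particular
threshold value transfers to clinical data.

## 6. Verification conditions that needed care

Two test constructions deserve explanation, since their conditions are
part of the package's design:

* **Rater recovery prevalence.** The recovery battery plants
  $(p_j, q_j) \in [0.80, 0.99]$ for 5 raters on a ~131k-voxel grid and
  requires recovery within ±0.02. Because $\gamma$ is fixed at the mean
  observer occupancy rather than estimated, it is exactly calibrated only
  when foreground and background are balanced; at low prevalence (~13 %)
  the prior bias alone moves worst-case sensitivity errors to the 0.02
  edge. The battery therefore uses a balanced (50 % foreground) truth —
  under iid flips the truth's geometry carries no information about the
  raters, so this is the neutral condition under which ±0.02 recovery is
  well-posed. Observed errors are then below 0.005.

* **Isocontour identifiability.** Recovering a planted threshold to
  ±0.5 points requires that neighbouring thresholds actually change the
  segmentation. Blurring a *voxelized* truth with a PSF comparable to the
  voxel size quantizes edge values into a few discrete levels (partial
  sums of a 2–3-tap kernel), leaving holes wider than 10 % of SUVmax in
  the value spectrum — on the 4 mm study grid the planted threshold is
  simply not identifiable at 0.5 % granularity, for any algorithm. The
  recovery battery therefore runs on a 2 mm isotropic grid where the
  blurred edge is finely sampled; the planted threshold is recovered in
  20/20 phantoms there.

## 7. Known limitations

* Binary STAPLE only; no spatial regularization, so scattered
  false-positive voxels from very noisy raters can enter the consensus at
  low prior mass.
* Sensitivity/specificity are defined relative to the restricted analysis
  region; they are not comparable across fits with very different region
  sizes.
* Hausdorff distances are voxel-centre distances; on coarse grids they are
  quantized to the spacing.
* The threshold sweep optimizes mean Dice only; volume-error or
  distance-based selection criteria are not implemented.
* NIfTI is the only format; DICOM-RT structure sets must be converted
  externally (e.g. with standard RT-struct conversion tools) and
  resampled to the PET grid beforehand.
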