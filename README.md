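# stapleseg

Multi-observer tumour delineation analysis for PET-guided radiotherapy
planning: STAPLE consensus contours, inter-observer variability (IOV)
metrics, and SUVmax-percentage threshold segmentation.

## The problem

When several radiation oncologists contour the same tumour — for example a
meningioma imaged with somatostatin-receptor PET on top of CT/MRI — their
gross tumour volumes (GTVs) disagree, and that disagreement is one of the
largest sources of uncertainty in radiotherapy planning. Quantifying the
disagreement needs three things:

1. **A reference contour.** `staple()` implements binary STAPLE
   (simultaneous truth and performance level estimation): the unknown true
   segmentation `T_i` is latent, each observer `j` is a rater with unknown
   sensitivity `p_j = P(D_ij = 1 | T_i = 1)` and specificity
   `q_j = P(D_ij = 0 | T_i = 0)`, and EM alternates between the voxelwise
   posterior

   ```
   a_i = γ ∏_j p_j^D_ij (1 − p_j)^(1 − D_ij)
   b_i = (1 − γ) ∏_j (1 − q_j)^D_ij q_j^(1 − D_ij)
   W_i = a_i / (a_i + b_i)
   ```

   and the M-step updates `p_j = Σ W_i D_ij / Σ W_i`,
   `q_j = Σ (1 − W_i)(1 − D_ij) / Σ (1 − W_i)`. The consensus mask is
   `W_i ≥ 0.5`.

2. **Agreement metrics.** `dice()` (`2|A∩B| / (|A|+|B|)`), `hausdorff()`
   (largest nearest-boundary distance in mm, computed between voxel centres
   via a Euclidean distance transform) and `mask_volume()` (cm³), per
   (lesion, observer, condition) via `compute_iov()`, compared between
   imaging conditions with a paired Wilcoxon signed-rank test
   (`compare_modalities()`).

3. **A semi-automatic segmentation to benchmark.** `threshold_segment()`
   grows the 26-connected component of `{SUV ≥ t% · SUVmax}` containing the
   lesion's SUVmax voxel; `sweep_thresholds()` scans t = 0…100 % in 0.5 %
   steps and selects the t maximizing the mean Dice against the consensus;
   `evaluate_on_validation()` applies the selected t to an independent
   lesion set; `correlate_threshold_volume()` checks (Spearman) whether the
   per-lesion optimum is just a surrogate for lesion size.

Because clinical contour sets are rarely shareable, the package ships a
synthetic study generator (`make_phantom()`, `simulate_observers()`,
`make_study()`): ellipsoidal lesions on a PET-like grid with Gaussian PSF
blur and noise, optional pituitary-like decoy hot spots, and observers with
either iid voxel flips (the exact STAPLE generative model) or smooth
boundary perturbations resembling real contouring variation. Every pipeline
stage is testable against planted ground truth.

## Worked example

```r
library(stapleseg)

study <- make_study(n_lesions = 6, seed = 11)   # two-condition synthetic study
fit <- staple(study$lesions[[1]]$observers$MRI_PET)
fit
#> Binary STAPLE consensus fit
#>   5 observers, foreground prior 0.009524, 13 EM iteration(s), converged
#>       sensitivity specificity
#> obs01      0.4305      1.0000
#> obs02      0.5740      1.0000
#> obs03      0.7940      0.9994
#> obs04      0.6478      0.9991
#> obs05      0.8956      0.9982

iov <- compute_iov(study)
head(iov, 3)
#>   lesion_id observer_id modality      dice hausdorff_mm volume_cm3 consensus_volume_cm3
#> 1  lesion01       obs01      MRI 0.7042254     7.549834       2.32                 3.36
#> 2  lesion01       obs02      MRI 0.8051948     5.656854       2.80                 3.36
#> 3  lesion01       obs03      MRI 0.7764706     5.656854       3.44                 3.36

compare_modalities(iov, "dice")
#> Paired Wilcoxon signed-rank: dice, MRI vs MRI_PET
#>   means: MRI = 0.7466, MRI_PET = 0.7841
#>   n = 30 pairs (30 non-zero), V = 177, p = 0.2579 (alpha 0.05)
```

Each IOV row scores one observer's contour against the STAPLE consensus of
its own imaging condition; here the PET-informed condition has the higher
mean Dice (the planted effect — at 6 lesions the paired test is not yet
significant, at the default 27 it is). The threshold sweep runs against the
PET-informed consensus:

```r
pet_sets <- lapply(study$lesions, function(l) l$observers$MRI_PET)
refs <- lapply(pet_sets, function(s) consensus_mask(staple(s)))
lesions <- lapply(study$lesions, function(l)
  list(pet = l$pet, roi = default_roi(l$observers$MRI_PET), lesion_id = l$lesion_id))
sw <- sweep_thresholds(lesions, refs)
sw
#> SUVmax-percentage threshold sweep
#>   6 lesion(s), thresholds 0..100% in steps of 0.5
#>   best threshold: 36.0% of SUVmax (mean Dice 0.915)

correlate_threshold_volume(sw$per_lesion_best, sapply(refs, mask_volume))
#> Spearman rank correlation (threshold vs volume): rho = 0.257, p = 0.6583, n = 6
```

`plot(sw)` draws the per-lesion Dice-versus-threshold curves with each
lesion's optimum marked. `run_study()` drives the whole analysis (IOV,
paired tests, sweep, validation group, correlation) from one config list or
YAML file and writes `iov.csv`, `sweep.csv`, `stats.json` and a manifest.

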