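---
title: "Delineating epilepsy-surgery resection cavities in pre-operative space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating epilepsy-surgery resection cavities in pre-operative space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After resective epilepsy surgery, studies that relate removed tissue to
outcome need a binary *resection mask* — a labelling of the voxels of the
**pre-operative** T1-weighted scan that were subsequently removed. Drawing
such masks by hand is slow and requires surgical anatomy expertise, and the
obvious automated shortcut — segmenting the fluid-filled cavity in the
post-operative scan and mapping it back — systematically misrepresents the
resection, because brain tissue *sags* into the cavity after surgery: tissue
visible inside the cavity footprint on the late post-operative scan was not
resected, and the cavity rim no longer coincides with the removed-tissue
boundary. `resectr` implements a fully automated three-part pipeline that
addresses this, together with the mask-agreement statistics used to evaluate
such pipelines and a synthetic phantom generator that makes every stage
testable against known ground truth.

## Pipeline

**Part A — data preparation.** Both scans are resampled to 1 mm isotropic
resolution (`normalize_resolution()`; the working field of view defaults to
256 mm per axis and the native grid is kept when the input is already 1 mm
isotropic). A region segmentation of each image — supplied externally by a
whole-brain segmenter, or by the phantom's ground truth — is merged into a
grey-matter *lobe atlas* (`build_lobe_atlas()`): Frontal, Parietal, Temporal,
Occipital, Insula and SubCortical per hemisphere, plus an `Excluded` class
for territories in which a resection cannot occur (ventricles, extracerebral
CSF, brainstem, cerebellum) and a `WM` placeholder for unassigned cerebral
white matter. The binarized atlas is the brain mask (`mask_brain()`). A
smooth multiplicative bias field is then estimated and removed
(`correct_bias()`), the top 1 % of brain intensities is clamped to the brain
median (`clamp_top_percentile()`), the grey-matter atlas is propagated
through the white matter so every brain voxel carries a lobe
(`dilate_atlas_through_wm()`), and the full atlas is split into the
user-specified resection territory and the remaining lobes
(`split_resection_lobes()`). The temporal-lobe filter deliberately includes
the subcortical and insular territories, since mesial structures are
routinely part of temporal resections. Defaults search both hemispheres and
all lobes.

Note on ordering: bias correction here runs *after* brain-mask assembly
because the estimator fits log-intensities within the brain; the clamp runs
last, within the brain only, since background zeros would distort the
percentile and the median.

**Part B — registration.** The post-operative image is aligned to the
pre-operative image by a rigid stage (`register_rigid()`) followed by a
demons-style deformable stage (`register_deformable()`), both multi-
resolution (4x, 2x, 1x) with fixed iteration schedules (100, 50, 25) and a
masked mean-squared-difference criterion on unit-rescaled intensities —
appropriate for same-modality T1–T1 alignment. The rigid stage is BFGS with
finite-difference gradients; because trilinear interpolation makes the cost
only piecewise smooth, the finite-difference step is scaled per level so a
probe rotation moves the brain periphery by a fixed fraction of the level's
voxel, and a derivative-free simplex polish runs at the finest level. The
deformable stage uses the Thirion force with the fixed-image gradient, a
per-voxel one-voxel cap on the raw update (the nominal step bound,
0.5/|gradient|, is unbounded in flat regions), Gaussian smoothing of the
update (sigma 1 voxel) and of the accumulated field (sigma 2 voxels), and
sets the field to zero outside the brain mask plus a 3-voxel margin. Both
stages are free of stochastic sampling, so repeated runs are bit-identical.
The resulting `transform_chain()` moves any post-operative payload
(intensities, labels, masks) onto the pre-operative grid with a single
interpolation — linear for intensities, nearest for labels, linear plus a
0.5 threshold for masks.

**Part C — cavity classification.** All steps run on the pre-operative grid.

1. Both images are robustly rescaled to [0, 1] within the brain
   (`rescale_unit()`, 1st/99th percentile), so CSF, grey and white matter
   take comparable values across scans.
2. A two-class Gaussian-mixture EM with *prior label* initialisation
   (`prior_mixture_segment()`) classifies the registered post-operative
   intensities inside the resection territory: class 1 is pinned to the
   ventricle prior (CSF), class 2 to cerebral tissue of the non-resected
   lobes. The class-1 voxels of the search region are the post-operative
   cavity estimate. When no lobe prior is given, a provisional
   ventricle-seeded run supplies the tissue prior.
3. A deterministic two-means split of the cavity intensities
   (`kmeans2_csf()`) separates fluid from damaged tissue; the cluster with
   the lower median intensity is the cavity CSF.
4. The difference image, pre minus registered post, masked to the
   pre-operative brain (`subtract_images()`), is positive where
   pre-operative tissue overlies post-operative fluid.
5. A second prior-guided EM expands the cavity through the difference image
   (`expand_cavity()`), seeded by the full step-2 cavity (the step-3 CSF
   subset is kept for step 7); the largest 26-connected component inside
   the resection territory survives. Seeding with the full cavity rather
   than its CSF subset follows the pipeline's bias goal — err toward
   over-coverage, which a human reviewer can trim, rather than silently
   under-cover sagged tissue.
6. Registration residue is removed (`remove_misalignment_spurs()`): erode by
   one voxel (unit Chebyshev ball, so voxels held up only by a thin bridge
   erode away too), keep the largest core, then re-grow by three constrained
   dilations inside the original mask, discarding newly reached 26-connected
   clusters smaller than `max(10, 1 %)` of the mask and barring them from
   later rounds. Narrow necks and their attachments drop off; solid shapes
   are restored exactly. If the erosion would empty the mask (small
   lesionectomies) the step is skipped with a warning.
7. A directional boundary dilation (`directional_boundary_dilation()`)
   extends the mask to the fluid boundary: every boundary voxel within 3
   voxels (Chebyshev; Euclidean by option) of CSF gains the voxels on the
   discrete segment toward the nearest such CSF voxel. The CSF map is the
   union of the step-3 cavity CSF, the full low-intensity class (below 0.2
   rescaled) of the registered post-operative image, and pre-operative
   low-intensity voxels outside the resection territory. The operator is
   applied to a fixed point (at most 10 passes): a single pass adds only
   strictly-between voxels, so a boundary starting more than two voxels from
   the fluid would stop short of the tissue boundary it is meant to reach.
8. Finalisation (`finalize_mask()`): morphological closing, filling of
   internal holes (6-connected background components not touching the
   volume border), multiplication by the pre-operative resection territory,
   reduction to a single 26-connected component, and resampling to the
   original pre-operative grid.

`run_cavity_pipeline()` orchestrates the three parts, retains every
intermediate for audit, and reports per-step voxel counts, the estimated
transform, warnings and timings.

## Evaluation statistics

`compare_masks()` treats the manual/automated overlap as a confusion matrix
and derives the Dice similarity coefficient `2TP / (2TP + FP + FN)`, the
miss rate `FN / (TP + FN)`, the false discovery rate `FP / (TP + FP)` and an
*overlap* measure implemented as the Jaccard index `TP / (TP + FP + FN)` =
`DSC / (2 − DSC)`; a sensitivity reading (`TP / (TP + FN)`) is available by
option. `classify_dsc()` applies the conventional rubric with half-open bins
assigned upward: below 0.6 poor, 0.6–0.7 good, 0.7–0.8 high, 0.8 and above
excellent. `summarize_cohort()` reports medians and IQRs (quartiles by
linear interpolation, fixed for reproducibility) and rubric counts;
`wilcoxon_paired()` performs the paired signed-rank test with zero exclusion
and mid-rank ties, exactly (full randomisation distribution via a
generating-function convolution) up to n = 25 and by a tie-corrected,
continuity-corrected normal approximation beyond; `compare_pipelines()`
applies the conventional one-tailed directions (greater for DSC/overlap,
less for miss rate/FDR).

## The phantom

`generate_pre()` builds a layered ellipsoidal brain — white-matter core,
grey-matter shell, outer CSF rim, two ventricles, a subcortical grey nucleus
and an insular wedge per hemisphere — with lobes assigned by
anterior/posterior and superior/inferior quadrant around the volume centre,
split at the mid-sagittal plane. `apply_surgery()` carves an ellipsoidal
cavity (filled at the CSF mean), then applies, in order: a sagging
displacement pulling tissue toward the cavity centroid with magnitude
`s * exp(−d / 3 voxels)` in the unsigned distance `d` to the cavity wall; a
rigid patient-positioning offset; an independently drawn bias field (product
of per-axis degree-1 polynomials, peak deviation `bias_amplitude`,
normalised to mean 1 over the brain); and additive Gaussian noise. The
ground-truth mask is the set of carved voxels, defined before sagging and
misalignment. Region labels in the style of a whole-brain segmenter are
emitted for both time points; the post-operative labels mark the cavity as
extracerebral CSF, which is why the pipeline derives its search region and
priors from the *pre-operative* atlas.

Default conditions (chosen once, as plausible values for late post-operative
epilepsy imaging): 96^3 voxels at 1 mm; tissue means 0/80/160/240 for
background/CSF/GM/WM; noise 3 % of the WM mean (typical T1 SNR); bias
amplitude 10 %; sagging 2.5 voxels peak (a few millimetres of brain shift at
the cavity margin); rigid offset ~4 mm / ~3 degrees. `make_fixture_suite()`
emits the graded battery used throughout the tests: (a) aligned/noiseless,
(b) noise + bias, (c) sagging only, (d) misalignment only, (e) everything
combined, (f) a small lesionectomy (cavity volume below 5 % of the default).

**What the phantom does not emulate.** Intensities are piecewise constant:
there is no cortical folding, texture, or partial-volume structure. Noise is
Gaussian rather than Rician. Two consequences matter for interpreting green
tests. First, where *same-class* tissue sags into the cavity the moved
tissue is intensity-indistinguishable from what the pre-operative scan shows
at that location, so no intensity-driven method — including a perfect
correspondence field, which we verified by warping through the exact
fixed-point inverse of the generating deformation — can label that shell
from the images alone; the pipeline recovers it only where class contrast,
the fluid boundary, or the directional dilation reach it, and the
full-difficulty phantom therefore sits at a structural ceiling around DSC
0.79-0.82 depending on the noise draw (a per-voxel oracle over post-image
CSF-likeness and positive-difference thresholds does no better), with the
residual miss concentrated in the sag shell. On real images,
texture gives a deformable registration more to work with. Second, for the
same reason the masked-MSD gain of the deformable stage on a sagging-only
phantom is bounded by interface interpolation blur (the exact inverse field
achieves a ratio of about 1.0 at 48^3), so the registration tests assert
MSD halving on a recoverable large-scale deformation and non-degradation on
the sag field, rather than a halving the phantom cannot express.

## Numerical choices and degenerate inputs

* EM (both prior-guided stages): two Gaussian classes, fixed memberships for
  prior voxels, convergence when the largest parameter change falls below
  1e-5 or 100 iterations; standard deviations floored at 1e-3 so noiseless
  phantoms cannot degenerate; a warning is raised when the prior class means
  sit within 0.5 pooled SD. No MRF/ICM smoothing term.
* Two-means CSF split: Lloyd iterations from the 25th/75th percentile
  values; ties resolved toward the lower mean, then toward the cluster
  containing the minimum; a single-valued cavity returns whole with a
  warning.
* Connectivity: 26 for components and clusters, 6 for hole-filling
  background; the spur-removal erosion element is the unit Chebyshev ball
  (26-neighbourhood), general-purpose erosion defaults to the
  6-neighbourhood.
* Nearest-label atlas propagation: 6-connected breadth-first rounds,
  restricted to the voxel's hemisphere half-space; round ties break toward
  the lowest lobe code, then the lowest linear index; `Excluded` never
  propagates. Unreachable voxels (none in practice) fall back to `Excluded`
  with a warning.
* Quantiles everywhere use linear interpolation between order statistics
  (R type 7), fixed so medians and rescalings are reproducible.
* Empty results are errors with stage-named messages ("no cavity found",
  "cavity outside specified lobe"), never silent empty masks.

## Problem sizes

The test suite exercises the full pipeline at 96^3 (the battery's default)
for the acceptance-grade cases and at 48^3 for the remaining integration
and property tests; registration recovery is checked at both scales. These
sizes keep a full check run to a few minutes on a single CPU while leaving
the phantom anatomy (cavity of ~4000 voxels, ventricles, six lobes per
hemisphere) well resolved.

## Known limitations

* The pipeline consumes an external region segmentation; no skull stripping
  or network segmenter is bundled. The packaged lobe-mapping table covers
  the phantom's label scheme; real segmenter outputs need their own table
  (`--lobe-map`, or the `mapping` argument).
* The deformable stage is a compact demons implementation, not a
  reimplementation of symmetric diffeomorphic registration; a production
  deployment can substitute an external registration behind
  `transform_chain()`.
* Surface-distance metrics (Hausdorff, ASSD) and multiple-testing
  correction are out of scope; reported p-values are uncorrected.
* The sagging model is radial with exponential decay — adequate for testing
  the pipeline's change-detection logic, not a biomechanical model.
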