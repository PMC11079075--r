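---
title: "Adaptive histogram-based CBCT preprocessing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive histogram-based CBCT preprocessing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctools)
```

## The problem

Cone beam CT (CBCT) stores gray values on a scale that, unlike the
Hounsfield units of conventional CT, is not calibrated across devices. The
gray range, contrast and field of view vary with the manufacturer, the
reconstruction interpolation and the acquisition settings, so the common
"generic" preprocessing for segmentation networks — clip to the 0.5th and
99.5th percentiles and normalize — places the intensity window differently
on every scanner. For dental segmentation the informative tissue
(bone, teeth, the mandibular canal) occupies only the bright minority of
voxels; teeth alone are roughly 1–3% of the volume. A window anchored to
percentiles of the whole image wastes most of its dynamic range on air and
soft tissue and shifts across vendors.

`cbctools` implements an adaptive alternative: anchor the window to the one
histogram feature that every head CBCT shares, the soft-tissue peak.

## The model

The gray-value histogram of a head CBCT has a characteristic shape:

* one or two narrow **spikes** — voxels outside the reconstruction field of
  view and air voxels each share a single exact gray value;
* one broad **peak** from soft tissue;
* **no distinct mode** for bone, teeth or restorations, which smear into a
  long bright tail.

The pipeline treats the histogram as a 1-D signal:

1. **Bin** the gray values (default bin width 1 gray unit).
2. **Median-filter** the curve (default window 5 bins, symmetric-reflection
   edges) to delete the spikes.
3. **Detect the soft-tissue peak**: the highest local maximum whose width at
   half prominence is at least 5 bins and whose height reaches 0.1% of the
   voxel count. Ties break toward the lower gray value (soft tissue is
   darker than bone). If no peak qualifies the scan falls back to the
   percentile baseline with a warning.
4. **Fit a Gaussian** over a window of 200 gray units on both sides of the
   peak midpoint:
   \[
   f(x) = \frac{k}{\sqrt{2\pi}\,\sigma}
          e^{-\frac{(x-\mu)^2}{2\sigma^2}},
   \]
   by Levenberg–Marquardt least squares, initialized at
   \(\mu_0 = \text{peak midpoint}\), \(\sigma_0 = 200/6\),
   \(k_0 = y(\mu_0)\sqrt{2\pi}\sigma_0\), with \(\sigma > 0\) enforced.
5. **Derive the bone truncation value**
   \(x_b = x_s + d\) with \(d = c\,\sigma\). The soft-tissue value
   \(x_s\) is the fitted \(\mu\) by default and the factor defaults to
   \(c = 3\), the calibration that maximizes downstream segmentation
   accuracy in the ablation this method comes from.

Preprocessing for training then resamples to 0.4 mm isotropic voxels, clamps
gray values to \([x_b,\ P_{99.5}]\) and normalizes the volume to mean 0,
standard deviation 1. Because \(x_s\) and \(\sigma\) move affinely with the
gray scale, the whole window is equivariant under a vendor's affine
intensity transform — the property that makes the method adaptive, and the
one the acceptance script measures directly.

## Tunable parameters

| parameter | default | unit | notes |
|---|---|---|---|
| `bin_width` | 1 | gray units | the source method never states one; 1 resolves single-valued spikes |
| `median_kernel` | 5 | bins | removes 1–2-bin spikes without eroding the broad peak |
| `min_peak_width` | 5 | bins | width at half prominence |
| `min_peak_height_fraction` | 0.001 | fraction of voxels | 0.1% floor |
| `roi_halfwidth` | 200 | gray units | Gaussian fitting window half-width |
| `sigma_factor` | 3 | — | \(d = c\sigma\); exposed per scan/vendor |
| `target_spacing` | 0.4 | mm | isotropic resampling target |
| `upper_percentile` | 99.5 | % | upper clamp |
| `baseline_lower_percentile` | 0.5 | % | baseline path lower clamp |
| `crop_shape` | 96×160×160 | voxels | training crop |
| `mask_cube`, `mask_count_range` | 12, 0–16 | voxels, cubes | cutout masking |
| `flip_prob_per_axis` | 0.5 | — | mirror flips |

## Design decisions where the method left room

* **Peak width** is measured at half prominence in bins; the source gives
  the constraint values ("width 5, height 0.1%") but not the measurement
  convention.
* **\(x_s\)** is taken from the fitted \(\mu\) (the quantity the
  \(d = c\sigma\) calibration refers to); the raw filtered-curve midpoint is
  exposed via `x_s_source = "raw"`.
* **Clipping clamps rather than deletes**: a grid image cannot drop voxels,
  and clamping preserves geometry for cropping and evaluation.
* **The 99.5th percentile** is computed on the resampled, unclipped volume;
  computing it after removing sub-bone values would couple the two bounds.
* **Interpolation**: trilinear for images, nearest for labels, so label
  volumes can never acquire values absent from the input.
* **Percentiles** interpolate linearly between order statistics
  (`stats::quantile` type 7).
* **Flips** are independent per axis with probability 0.5; the recipe names
  the axes but not the probability.
* **Cutout count** is uniform on {0..16}; only the range is stated.
* **Augmentation randomness** comes from one stream per sample, consumed in
  the fixed order crop → flip → mask, so a single seed documents the whole
  transform.
* **Cross-entropy** is implemented exactly as printed — class-averaged
  (1/C) with no 1/N — so the value scales with patch size; a
  `per_voxel_mean` flag provides the patch-size-independent variant.
* **Soft Dice** guards classes absent from both prediction and truth with
  an additive denominator epsilon (1e-5) and a zero numerator; the printed
  form is recovered exactly whenever the class is present.
* **ASD is symmetric**, pooling the directed nearest-surface distances from
  both sides; the prose definition is one-directional, and pooling is the
  common symmetric reading.
* **HD is the exact maximum**; a 95th-percentile variant exists
  (`percentile = 95`) but is off by default because the prose says maximum.
* **mIoU excludes background** by default; including it inflates scores.
* **Vacuous classes** (absent from both volumes) report Dice 1 with status
  `"vacuous"` and are excluded from aggregates.

## Numerical choices

* The Gaussian fit runs Levenberg–Marquardt (`minpack.lm::nlsLM`) from the
  prescribed start; if that start sits on a degenerate point of the numeric
  Jacobian (for example \(\mu_0\) exactly 0, where relative
  finite-difference steps vanish) it is nudged off zero and, on failure,
  refit from moment estimates of the window. \(\sigma\) is bounded below at
  1e-6; a fit ending on the bound or with \(\mu\) outside the window raises
  a fit-failure condition with a machine-readable reason.
* Surfaces are mask voxels with at least one of six face neighbours in the
  background (the grid border counts as background). Surface distances are
  Euclidean between voxel centres in mm, honouring anisotropic spacing,
  computed with an exact squared Euclidean distance transform
  (lower-envelope-of-parabolas, implemented in C++), cropped to the joint
  bounding box. Unit and acceptance tests arbitrate the transform against
  an all-pairs brute-force oracle.
* Histograms span `[min, max]` of the volume with every voxel counted
  exactly once; median filtering uses symmetric reflection at the edges.
  `adaptive_threshold()` shrinks the median window to the largest odd
  length that fits a degenerate (near-constant) histogram, so such volumes
  reach the no-peak error path instead of a kernel error.
* Zero-variance volumes after clamping, empty masks, mismatched grids,
  unknown labels and invalid FDI codes all raise typed conditions
  (`cbctools_error_*`), never silent NaNs.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a parametric head: an ellipsoidal soft-tissue
volume, two circular-arc bone arches, up to 32 FDI-coded tooth ellipsoids
placed along the arches, a tubular mandibular canal inside the mandible, two
ellipsoidal air-filled maxillary sinuses, and an optional outside-FOV
cylinder. Labels are the exact pre-noise geometry. Defaults
(96×96×80 voxels at 0.4 mm, soft tissue N(300, 40), bone at +400, teeth at
+700, air exactly 0, outside-FOV exactly −500, tooth-fraction target 0.02)
were chosen once to reproduce the assumed histogram structure: air and FOV
voxels hold one exact value each (the spikes), soft tissue is the only
Gaussian mode, and the bone/teeth separation of 10 soft-tissue standard
deviations matches the clear visual separation of real scans. Adjacent
tooth ellipsoids overlap slightly along the arch, so the achieved tooth
fraction lands near 0.013 — inside the 1–3% band reported for real
dentitions.

Mineralized-tissue gray values are spread **uniformly** over ±6
`noise_sd` around their base rather than drawn from a Gaussian: at
desk-scale voxel counts a narrow Gaussian bone class would form a
qualifying histogram peak of its own (real CBCT bone does not), while an
unbounded Gaussian wide enough to flatten that mode would push part of the
bone below any reasonable clip. The bounded band keeps both stated
properties — no distinct mineral mode, and essentially all bone above
\(x_b\) — simultaneously. With `noise_sd = 0` every labeled voxel carries
exactly its class base intensity, which is how the geometry/intensity
contract is tested.

The phantom does **not** emulate anatomy (shapes are ellipsoids and tubes),
metal artifacts, beam hardening, motion blur, spatially correlated noise,
or scanner-specific nonlinearities. Passing tests therefore demonstrate the
algorithmic contracts — peak detection, fit recovery, affine equivariance,
metric correctness — not clinical segmentation accuracy on real scans,
which requires real data and trained networks and is out of scope here.

Six synthetic affine `manufacturer_profiles()` (scale 0.6–2.4, shift −150
to +500) stand in for cross-vendor variability; the names are generic and
the values invented.

## Problem sizes used by the tests and the acceptance script

Fit recovery runs a 132-point noiseless (μ, σ) grid plus 100 noisy
replicates; threshold behaviour uses 20 phantoms at the default 96×96×80
grid with soft-tissue means 260–355 and standard deviations 30–50; metric
oracle equivalence uses 100 random mask pairs of at most 1000 voxels;
end-to-end degradation sweeps rigid shifts of 0–3 voxels on a full default
phantom. These sizes keep the whole suite under a minute on one CPU while
exercising every contract at realistic parameter ranges.

## Known limitations

* I/O is NIfTI only; NRRD and DICOM series should be converted upstream.
  Volumes are processed in stored voxel order; xform rotations are carried
  through but not resampled to a canonical orientation.
* The printed cross-entropy grows linearly with the number of voxels; use
  `per_voxel_mean = TRUE` when comparing losses across patch sizes.
* Scans with severe metal artifacts can distort the bright tail; the method
  makes no attempt at artifact reduction, and a scan whose histogram has no
  qualifying soft-tissue peak silently (but loudly warned) falls back to
  the percentile baseline.
* `sigma_factor = 3` is a global default; whether the optimal factor is
  universal or vendor-specific is unresolved, so it is a per-run parameter.
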