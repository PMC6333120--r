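---
title: "Multi-atlas synthetic CT from Dixon MRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas synthetic CT from Dixon MRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MR-only radiotherapy planning of the pelvis needs electron-density
information that MRI does not provide. A synthetic CT (sCT) assigns a
Hounsfield-unit value to every MR voxel so dose can be computed without a
planning CT. `masct` implements a multi-atlas approach: a library of
co-registered CT–MR pairs is deformed onto a new subject's MR, and the
atlas CT values are fused voxel-by-voxel with weights derived from the
local quality of each registration.

The pipeline has five stages, all exposed as ordinary R functions and as
`atlas-sct` subcommands:

1. **MR conditioning** — per-slice bias-field reduction, landmark-based
   histogram standardization of the Dixon water- and fat-only series, and
   the fat-enhanced water blend
   \(MR_{W,FE} = (MR_{S,W} + \alpha\, MR_{S,F})/(1+\alpha)\), default
   \(\alpha = 0.5\). The blend improves fat/air discrimination: on a
   water-only image both fat and air are dark, which starves the MR-to-MR
   registration of gradient information at the subcutaneous boundary.
2. **CT conditioning** — air removal (HU < −250, strict), three-class fuzzy
   c-means into fat/muscle/bone, bone suppression to air HU, and a
   piecewise-linear remap that places the fat and muscle cluster centers at
   the water image's dark and bright landmarks. The conditioned CT
   (`CT_S,BS,FS`) looks like a water MR image, so the cross-modality CT→MR
   registration can use a plain mean-squared-error cost.
3. **Registration** — landmark-initialized rigid alignment (orthogonal
   Procrustes on trochanter-style points) followed by a cubic B-spline
   free-form deformation optimized by L-BFGS-B with an analytic gradient
   over a 3-level coarse-to-fine pyramid. The fitted field is applied to
   the *original* planning CT to build the atlas pair `(CT_reg, MR_W,FE)`.
4. **Propagation + fusion** — every atlas pair is registered onto the
   target's `MR_W,FE`; per voxel and per atlas the generalized registration
   error
   \(GRE = \big((m^2+\varepsilon)(\sigma^2+\varepsilon)(H+\varepsilon)\big)^{1/3}\)
   (squared mean, population variance and Shannon entropy of the in-plane
   patch difference) is minimized over a 2-mm in-plane offset search, and
   the synthetic CT is the \(1/GRE\)-weighted average of the
   offset-corrected atlas CT values.
5. **Evaluation** — mean absolute error (HU) against a reference CT over
   the entire body and the bone/fat/muscle regions, with leave-one-out and
   train/test drivers.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `alpha` | 0.5 | – | fat-enhancement blend weight |
| air threshold | −250 | HU | strict `<` cut separating air from tissue on CT |
| standard scale | 100 / 500 / 1000, cap 1200 | a.u. | targets for dark mode / valley / bright mode; only relative placement matters, a fixed frame makes atlas and target comparable |
| `grid_spacing_mm` | 20 | mm | B-spline control spacing; must be finer than the deformation scale to be recovered |
| `iterations_per_level` | 100/60/25 | – | L-BFGS-B iterations, coarse to fine |
| `regularization_weight` | 0.1 | – | bending-energy penalty on the control lattice |
| `patch_radius_vox` | 2 | voxels | 5×5 in-plane GRE patch |
| `entropy_bins` | 32 | – | equal-width bins over the patch's own range |
| `epsilon` | 1e-6 | – | additive floor inside each GRE factor |
| `search_radius_mm` | 2.0 | mm | in-plane best-match search radius |

Three registration defaults deviate from the obvious first guess and were
fixed by parameter-recovery experiments on the phantom (the source method
delegated registration to an external tool and states only the cost
function and that no subsampling was used):

* **Control spacing 20 mm** (not 40 mm). The phantom's inter-subject
  deformations have a ~15 mm correlation scale; a 40 mm lattice cannot
  represent them and recovery stalls at the unregistered baseline. 20 mm
  recovers a 5 mm-amplitude field to well under 2 mm mean error while a
  15 mm lattice already starts chasing noise (image MSE keeps falling while
  the field error rises).
* **Bending weight 0.1** (not 0.01), damping noise-driven warps inside
  homogeneous tissue where the MSE cost carries no information (the
  aperture problem).
* **Clamp-to-edge sampling near the moving-image border** inside the cost
  function only. A hard out-of-support fill makes the cost discontinuous —
  an infinitesimally small boundary crossing flips a voxel from its image
  value to the fill value — which reliably breaks the L-BFGS-B line search.
  User-facing warps (`apply_deformation`, `resample_to`) use voxel-as-cell
  support — points up to half a voxel beyond the outer sample centres are
  sampled clamped to the edge, anything farther takes the modality-default
  fill (−1000 HU for CT, 0 for MR and masks). Without the half-voxel shell
  a sub-voxel displacement at a volume face flips whole boundary slices to
  the fill value.

Two further choices where the design was genuinely open:

* **Foreground for landmark detection.** An Otsu threshold on the whole
  image was the first candidate for excluding the air background, but on
  pelvis-like intensity distributions the maximal between-class-variance
  split can land *between fat and muscle* (air + fat + bone vs muscle),
  silently dropping fat from the dark cluster. `background_threshold()`
  instead takes the first local minimum of the smoothed histogram after the
  dominant dark (air) peak, falling back to Otsu when no such peak exists.
* **GRE conventions.** The patch is 2-D in-plane (5×5) so that the metric
  and the 2-D offset search live in the same plane; entropy is Shannon,
  base 2, over equal-width bins spanning the patch's own range (a constant
  patch has entropy 0); ε is added *inside* each factor so that a constant
  nonzero difference (variance = entropy = 0 but squared mean > 0) is not
  mistaken for a perfect match; the fusion weight uses the searched minimum
  GRE together with its offset.

## The phantom: what it emulates, what it does not

`make_cohort()` generates paired CT / water / fat volumes
(default 96×96×48 voxels at 1×1×2.5 mm) from a deterministic pelvis-like
template: an elliptical body with a subcutaneous fat ring, muscle interior,
two femoral-head spheres, a pelvic-ring shell, a sacrum block and one
interior air pocket. Per subject the template is warped by a seeded smooth
random field (white noise smoothed to ~15 mm correlation, rescaled to a
5 mm maximum by default); intensities are drawn per tissue (CT: air −1000,
fat −100 ± 15, muscle +40 ± 10, bone +700 ± 100 HU — generator conventions,
not claims about any scanner); the MR channels are corrupted by a smooth
multiplicative gain (±20 % default) and Rician noise (σ = 15), matching the
magnitude statistics of MR while CT noise stays Gaussian per tissue.
Landmarks (femoral-head centers, sacrum, an anterior marker) are mapped
through the inverse warp so they stay attached to the anatomy, which gives
the rigid initialization four exact non-collinear points per subject.

The generator reproduces the statistical structure the method assumes —
water-image muscle is the bright mode and fat dark, fat-image fat bright,
three non-air CT modes — and it provides ground-truth labels and the true
deformation, so registration recovery and synthesis MAE are computable
without circularity. It does **not** model Dixon reconstruction physics,
fat–water swaps, metal or motion artifacts, end-slice artifacts, couch
structures, or realistic anatomy. A green end-to-end test therefore
establishes that the pipeline's machinery is correct and numerically
stable, not that clinical accuracy claims transfer.

## Numerical conventions

* Volumes are column-major arrays with world mapping
  `origin + direction %*% (index * spacing)`, 0-based indices, mm units;
  sagittal slices along the first axis, axial along the third. Bias
  correction runs per sagittal slice; the GRE patch and search are axial
  in-plane.
* NIfTI-1 is the interchange format. The float32 sform is written for
  interoperability and the exact float64 geometry travels in a JSON header
  extension, so round-trips preserve geometry exactly and data to float32.
* Deformation fields are pull-back maps on the fixed grid (`out(x) =
  moving(x + d(x))`), stored as (nx, ny, nz, 3) arrays of mm displacements.
* FCM uses fuzzifier 2, tolerance 1e-4 on the centers, seeded
  k-means++ initialization; clustering subsamples large inputs (seeded) and
  assigns the full data by nearest center afterwards, keeping results
  deterministic. The registration, fusion and phantom kernels contain no
  unseeded randomness, so identical seeds give byte-identical outputs.
* Search offsets are pre-sorted by physical magnitude, then
  lexicographically; the first strict GRE minimum wins, which implements
  the tie-break (smaller offset, then row before column).
* Degenerate inputs: constant images and all-air CTs raise degenerate-input
  errors; all-zero sagittal slices are skipped with gain 1 and a warning;
  a histogram with no interior minimum falls back to the midpoint of the
  two modes with a warning.

## Known limitations

* The bias model (per-slice 2nd-order polynomial gain, three intensity
  classes, 20 alternations) is a smooth-basis realization of
  local-clustering bias correction; equivalence to any specific published
  algorithm is not claimed — the tested property is per-tissue
  coefficient-of-variation reduction.
* Self-consistency of an atlas pair (CT and MR of the same subject already
  aligned) is limited by sub-voxel jitter: warping a noisy image by even
  0.3 mm changes bone-region voxels by tens of HU, so the "identity"
  registration is only exact on noise-free volumes.
* The fused CT inherits the usual multi-atlas blur; no sharpening is
  applied. Bone remains the dominant error region.
* Only MSE on conditioned images is supported as a registration cost;
  mutual information and diffeomorphic constraints are out of scope, as are
  dose recalculation, DVH and gamma analysis.
* DICOM import is a convenience for uncompressed single-frame,
  explicit-VR-little-endian series; DICOM-RT objects are out of scope.
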